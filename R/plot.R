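#' Render a snapshot with the standard tissue palette
#'
#' MEP in blue, LEP in green, necrotic debris in red, medium in white;
#' thin grey cell boundaries between distinct agent indices.
#'
#' @param object a `dcis_snapshot`.
#' @param boundaries draw cell-cell boundaries?
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dcis_snapshot <- function(object, boundaries = TRUE, ...) {
  ty <- type_raster(object)
  lat <- object$lattice
  df <- tibble::tibble(
    x = as.vector(row(ty)), y = as.vector(col(ty)),
    type = factor(type_label(as.vector(ty)), levels = TYPE_LEVELS)
  )
  pal <- c(MEDIUM = "white", LEP = "#2e9e4f", MEP = "#2a63c9",
           NECROTIC = "#d22d2d")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$type)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = sprintf("%s duct, MCS %d",
                                  object$geometry$archetype, object$mcs),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (boundaries) {
    W <- nrow(lat); H <- ncol(lat)
    vb <- which(lat[-W, ] != lat[-1, ], arr.ind = TRUE)
    hb <- which(lat[, -H] != lat[, -1], arr.ind = TRUE)
    seg <- dplyr::bind_rows(
      tibble::tibble(x = vb[, 1] + 0.5, xend = vb[, 1] + 0.5,
                     y = vb[, 2] - 0.5, yend = vb[, 2] + 0.5),
      tibble::tibble(x = hb[, 1] - 0.5, xend = hb[, 1] + 0.5,
                     y = hb[, 2] + 0.5, yend = hb[, 2] + 0.5)
    )
    p <- p + ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                               yend = .data$yend),
      inherit.aes = FALSE, linewidth = 0.1, colour = "grey40")
  }
  p
}

#' Phase-diagram tile plot of sweep consensus verdicts
#'
#' Consensus morphology per (mitotic events, apoptosis probability)
#' condition, mirroring the standard proliferation-by-apoptosis grids.
#'
#' @param results a sweep results tibble.
#' @param at_mcs checkpoint MCS.
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(results, at_mcs = NULL) {
  cons <- sweep_consensus(results, at_mcs = at_mcs)
  pal <- c(normal = "grey90", micropapillary = "#9ecae1",
           cribriform = "#fdd0a2", solid = "#a1d99b", comedo = "#de2d26",
           mixed = "grey60")
  ggplot2::ggplot(cons, ggplot2::aes(
    x = factor(.data$n_events),
    y = factor(100 * .data$apoptosis_prob),
    fill = .data$consensus)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = "mitotic events per 1000 MCS",
                  y = "apoptosis probability (%)", fill = "consensus") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-region invasion frequencies
#'
#' @param results replicate results over cylinder / bifurcation runs.
#' @param at_mcs checkpoint MCS.
#' @return A ggplot object.
#' @export
plot_invasion <- function(results, at_mcs = NULL) {
  inv <- invasion_count(results, at_mcs = at_mcs) |>
    tidyr::pivot_longer(c("end_fraction", "duct_fraction"),
                        names_to = "region", values_to = "fraction") |>
    dplyr::mutate(region = sub("_fraction", "", .data$region))
  ggplot2::ggplot(inv, ggplot2::aes(x = .data$preset, y = .data$fraction,
                                    fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(end = "#d95f02", duct = "#7570b3")) +
    ggplot2::labs(x = NULL, y = "fraction of replicates with invasion",
                  fill = "region") +
    ggplot2::theme_minimal()
}
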