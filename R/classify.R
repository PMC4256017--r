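#' Segment enclosed lumena in a snapshot
#'
#' Connected components (4-connectivity) of medium pixels enclosed by the
#' tissue, i.e. not connected to the exterior medium; pockets smaller than
#' half a cell area are discarded as lattice noise.
#'
#' @param snap a `dcis_snapshot`.
#' @param min_px minimum component area in pixels.
#' @return A tibble with one row per lumen: `lumen`, `area`, centroid
#'   `x`, `y`.
#' @export
segment_lumena <- function(snap, min_px = 50) {
  med <- (snap$lattice == 0L) * 1L
  lab <- cc_label(med, eight = FALSE)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0]
  ids <- setdiff(unique(as.vector(lab)), c(0L, border))
  if (!length(ids)) return(tibble::tibble(lumen = integer(), area = integer(),
                                          x = numeric(), y = numeric()))
  rows <- lapply(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    c(area = nrow(w), x = mean(w[, 1]), y = mean(w[, 2]))
  })
  m <- do.call(rbind, rows)
  out <- tibble::tibble(lumen = seq_along(ids), area = as.integer(m[, "area"]),
                        x = m[, "x"], y = m[, "y"])
  out[out$area >= min_px, ]
}

# total enclosed medium area, unfiltered (solid criterion)
enclosed_medium_area <- function(snap) {
  med <- (snap$lattice == 0L) * 1L
  lab <- cc_label(med, eight = FALSE)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sum(lab != 0 & !(lab %in% border))
}

#' Classify a snapshot into a DCIS morphology
#'
#' Decision cascade over the four histological DCIS morphologies plus
#' `normal`:
#' 1. necrotic debris present -> `comedo` (solid with a necrotic core);
#' 2. enclosed medium smaller than one cell area -> `solid` (filled duct);
#' 3. at least two lumena and a LEP bridge spanning the duct (an
#'    8-connected LEP path between two monolayer wall cells whose chord
#'    passes within half a lumen radius of the duct axis) -> `cribriform`;
#' 4. LEP strictly inside the original monolayer (center of mass deeper
#'    than half a cell diameter into the initial lumen) with a patent
#'    lumen -> `micropapillary`;
#' 5. otherwise `normal`.
#'
#' The verdict is a pure function of the snapshot. The returned evidence
#' includes a `cribriform_with_necrosis` flag marking comedo verdicts in
#' which a spanning bridge and multiple lumena are also present.
#'
#' @param snap a `dcis_snapshot`.
#' @param min_lumen_px minimum lumen size passed to [segment_lumena()].
#' @return A one-row tibble: `verdict` plus evidence columns (`n_lumena`,
#'   `lumen_area`, `lumen_fraction` of the initial lumen area,
#'   `n_luminal_lep`, `n_necrotic`, `bridge`, `cribriform_with_necrosis`).
#' @export
classify_morphology <- function(snap, min_lumen_px = 50) {
  g <- snap$geometry
  ag <- snap$agents
  live <- ag[ag$status == "active", ]
  n_necrotic <- sum(live$type == "NECROTIC")
  lumena <- segment_lumena(snap, min_px = min_lumen_px)
  enc <- enclosed_medium_area(snap)
  cell_area <- pi * (g$cell_px / 2)^2
  # luminal LEP: live LEP that is not part of the monolayer wall (no
  # contact with MEP) and whose center of mass lies deeper than half a
  # cell diameter inside the initial lumen
  lep <- live[live$type == "LEP", ]
  wall <- wall_sigmas(snap)
  ix <- pmin(pmax(round(lep$x), 1L), nrow(g$dist_in_lumen0))
  iy <- pmin(pmax(round(lep$y), 1L), ncol(g$dist_in_lumen0))
  depth <- g$dist_in_lumen0[cbind(ix, iy)]
  n_luminal <- sum(depth > g$cell_px / 2 & !(lep$sigma %in% wall))
  bridge <- nrow(lumena) >= 2 && has_spanning_bridge(snap)
  verdict <-
    if (n_necrotic > 0) "comedo"
    else if (enc < cell_area) "solid"
    else if (bridge) "cribriform"
    else if (n_luminal >= 1) "micropapillary"
    else "normal"
  tibble::tibble(
    verdict = factor(verdict, levels = VERDICT_LEVELS),
    n_lumena = nrow(lumena), lumen_area = enc,
    lumen_fraction = enc / sum(g$lumen0),
    n_luminal_lep = n_luminal, n_necrotic = n_necrotic,
    bridge = bridge,
    cribriform_with_necrosis = n_necrotic > 0 && bridge
  )
}

# monolayer wall cells: LEP with a pixel 8-adjacent to a MEP pixel
wall_sigmas <- function(snap) {
  ty <- type_raster(snap)
  mepm <- ty == 2L
  if (!any(mepm)) return(integer())
  wall <- unique(snap$lattice[dilate_mask(mepm) & ty == 1L])
  wall[wall != 0]
}

# Is there a path of luminal (non-wall) LEP extending completely across
# the duct? A qualifying path is an 8-connected component of non-wall LEP
# pixels that touches at least two monolayer wall cells whose chord passes
# within half a lumen radius of the duct axis (roughly diametral). The
# wall ring itself is excluded from the path, so an intact monolayer never
# counts as a bridge.
has_spanning_bridge <- function(snap) {
  g <- snap$geometry
  ty <- type_raster(snap)
  mepm <- ty == 2L
  if (!any(mepm)) return(FALSE)
  wall <- wall_sigmas(snap)
  if (length(wall) < 2) return(FALSE)
  luminal_mask <- (ty == 1L & !(snap$lattice %in% wall)) * 1L
  dim(luminal_mask) <- dim(snap$lattice)
  if (!any(luminal_mask > 0)) return(FALSE)
  lab <- cc_label(luminal_mask, eight = TRUE)
  wall_raster <- matrix(0L, nrow(snap$lattice), ncol(snap$lattice))
  wpx <- snap$lattice %in% wall & ty == 1L
  wall_raster[wpx] <- snap$lattice[wpx]
  ag <- snap$agents
  half <- g$lumen_halfwidth / 2
  ax <- g$axis
  for (cid in seq_len(max(lab))) {
    comp <- lab == cid
    # wall cells 8-adjacent to this component
    touched <- unique(wall_raster[dilate_mask(comp) & wall_raster > 0])
    if (length(touched) < 2) next
    P <- as.matrix(ag[match(touched, ag$sigma), c("x", "y")])
    n <- nrow(P)
    if (n > 60) { P <- P[round(seq(1, n, length.out = 60)), , drop = FALSE]; n <- 60 }
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      mid <- (P[i, ] + P[j, ]) / 2
      k <- which.min((ax[, 1] - mid[1])^2 + (ax[, 2] - mid[2])^2)
      if (point_segment_dist(ax[k, 1], ax[k, 2], P[i, ], P[j, ]) <= half)
        return(TRUE)
    }
  }
  FALSE
}

point_segment_dist <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  l2 <- vx^2 + vy^2
  if (l2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- min(max(((px - a[1]) * vx + (py - a[2]) * vy) / l2, 0), 1)
  sqrt((px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2)
}

# binary dilation by the 3x3 box (8-neighbourhood)
dilate_mask <- function(m) {
  out <- m
  W <- nrow(m); H <- ncol(m)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 + dx):min(W, W + dx)
    xt <- max(1, 1 - dx):min(W, W - dx)
    ys <- max(1, 1 + dy):min(H, H + dy)
    yt <- max(1, 1 - dy):min(H, H - dy)
    out[xt, yt] <- out[xt, yt] | m[xs, ys]
  }
  out
}

#' Detect invasion through the myoepithelial layer
#'
#' The tissue envelope is the current MEP layer morphologically closed
#' with a disk of 2.5 cell diameters (so sheath gaps up to about five
#' cell diameters still count as the sheath) together with everything it
#' encloses. A live LEP whose center of mass lies more than one cell
#' diameter beyond the envelope has broken through the MEP layer into the
#' surroundings and counts as invasion; it is attributed to the region
#' (end or duct) of the nearest initial-footprint point. Gaps in the MEP
#' layer without such a cell are counted as breaches, not invasion —
#' scoring against the current sheath rather than the initial footprint
#' keeps ordinary duct expansion from reading as invasion.
#'
#' @param snap a `dcis_snapshot`.
#' @return A one-row tibble: `end_invasion`, `duct_invasion` (logicals),
#'   `n_invading`, `breach_count` and the invading agent indices as a
#'   list-column.
#' @export
detect_invasion <- function(snap) {
  g <- snap$geometry
  ag <- snap$agents
  lep <- ag[ag$status == "active" & ag$type == "LEP", ]
  env <- mep_envelope(snap)
  if (is.null(env)) {
    return(tibble::tibble(end_invasion = FALSE, duct_invasion = FALSE,
                          n_invading = 0L, breach_count = 0L,
                          invaders = list(integer())))
  }
  dm <- as.matrix(EBImage::distmap(EBImage::Image(1 - env$envelope)))
  ix <- pmin(pmax(round(lep$x), 1L), nrow(dm))
  iy <- pmin(pmax(round(lep$y), 1L), ncol(dm))
  outside <- dm[cbind(ix, iy)] > g$cell_px
  inv <- lep[outside, ]
  regions <- if (nrow(inv)) vapply(seq_len(nrow(inv)), function(i)
    nearest_region(g, inv$x[i], inv$y[i]), character(1)) else character()
  tibble::tibble(
    end_invasion = any(regions == "end"),
    duct_invasion = any(regions == "duct"),
    n_invading = nrow(inv),
    breach_count = env$breach_count,
    invaders = list(inv$sigma)
  )
}

# current MEP sheath envelope: the MEP mask closed with a 2.5-cell-diameter
# disk, plus everything not connected to the lattice border outside it.
# Breaches are sizeable openings of the sheath: components of the envelope's
# outer shell not covered by (dilated) MEP.
mep_envelope <- function(snap) {
  g <- snap$geometry
  ty <- type_raster(snap)
  mep <- ty == 2L
  if (!any(mep)) return(NULL)
  r <- round(2.5 * g$cell_px)
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  closed <- as.matrix(EBImage::closing(EBImage::Image(mep * 1), brush)) > 0
  lab <- cc_label((!closed) * 1L, eight = FALSE)
  ext <- lab[1, 1]
  envelope <- closed | (lab != ext)
  shell_brush <- EBImage::makeBrush(2 * g$cell_px + 1, shape = "disc")
  core <- as.matrix(EBImage::erode(EBImage::Image(envelope * 1), shell_brush)) > 0
  shell <- envelope & !core
  gaps <- shell & !dilate_mask(mep)
  glab <- cc_label(gaps * 1L, eight = TRUE)
  # a breach must open onto the enclosed interior (hole-filled region, not
  # material added by the closing itself, e.g. a branch-junction wedge)
  interior_fill <- envelope & !closed
  touching <- unique(glab[dilate_mask(interior_fill) & glab > 0])
  sizes <- tabulate(glab[glab > 0])
  real <- touching[sizes[touching] >= g$cell_px]   # ignore sliver artefacts
  list(envelope = envelope, breach_count = length(real))
}

#' Consensus verdict over replicate simulations
#'
#' The modal verdict if it reaches `threshold` (80% by default) of the
#' replicates, otherwise `"mixed"`.
#'
#' @param verdicts character or factor vector of per-replicate verdicts.
#' @param threshold consensus frequency required.
#' @return A length-1 character verdict.
#' @export
consensus_verdict <- function(verdicts, threshold = 0.8) {
  stopifnot(length(verdicts) >= 1)
  tab <- sort(table(as.character(verdicts)), decreasing = TRUE)
  if (tab[1] / length(verdicts) >= threshold) names(tab)[1] else "mixed"
}
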