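#' Choose which LEP divide at a scheduled mitosis round
#'
#' Samples `ceiling(division_fraction * n_LEP)` of the live LEP without
#' replacement (default: one quarter of them, resampled at every event).
#' With preferential proliferation on, cells whose center of mass lies in
#' an end region are sampled with `preferential_weight` times the weight
#' of duct-region cells, emulating the roughly two-fold higher division
#' frequency observed at the tips of engineered tissues.
#'
#' @param state a `cpm_state`.
#' @return Integer vector of selected agent indices (empty if no LEP
#'   remains alive).
#' @export
select_mitotic_cells <- function(state) {
  p <- state$params
  ag <- agents(state)
  lep <- ag[ag$type == "LEP" & ag$status == "active", ]
  if (nrow(lep) == 0) return(integer())
  k <- ceiling(p$division_fraction * nrow(lep))
  w <- rep(1, nrow(lep))
  if (isTRUE(p$preferential_proliferation)) {
    reg <- state$geometry$region
    ix <- pmin(pmax(round(lep$x), 1L), nrow(reg))
    iy <- pmin(pmax(round(lep$y), 1L), ncol(reg))
    in_end <- reg[cbind(ix, iy)] == 2L
    w[in_end] <- p$preferential_weight
  }
  as.integer(sample(lep$sigma, k, prob = w))
}

#' Divide one cell by a straight cut through its center of mass
#'
#' The cut orientation depends on the division-axis mode relative to the
#' local epithelial layer (the radial direction points from the nearest
#' medial-axis point to the cell): `"perpendicular"` cuts along the radial
#' direction, so both daughters stay within the layer; `"parallel"` cuts
#' along the tangential direction, pushing one daughter luminally;
#' `"random"` cuts at a uniformly random orientation. The daughter
#' receives a fresh index and the parent's type, targets and stiffnesses
#' (instantaneous division, no growth phase). If luminal-progeny
#' protection is enabled, the more luminal of the two records is exempted
#' from apoptosis checks.
#'
#' @param state a `cpm_state`.
#' @param sigma index of a live LEP with volume at least 2.
#' @param axis_mode override of the state's division-axis mode.
#' @return The daughter's agent index, or `NA` (with a warning) if the
#'   cell was too small to divide.
#' @export
divide_cell <- function(state, sigma, axis_mode = NULL) {
  p <- state$params
  mode <- axis_mode %||% p$axis_mode
  ag <- agents(state)
  row <- ag[ag$sigma == sigma, ]
  if (nrow(row) != 1 || row$status != "active")
    abort("sigma is not a live agent")
  if (row$V < 2) {
    warn(sprintf("cell %s has volume %s < 2; division skipped", sigma, row$V))
    return(NA_integer_)
  }
  dirs <- layer_direction(state$geometry, row$x, row$y)
  cut <- switch(mode,
    perpendicular = dirs$radial,
    parallel = dirs$tangential,
    random = { th <- runif(1, 0, 2 * pi); c(cos(th), sin(th)) }
  )
  d <- cpm_divide(state$ptr, as.integer(sigma), cut[1], cut[2])
  if (isTRUE(p$protect_luminal_progeny)) {
    ag2 <- agents(state)
    pr <- ag2[ag2$sigma %in% c(sigma, d), ]
    ax <- state$geometry$axis
    rad <- vapply(seq_len(nrow(pr)), function(i) {
      min(sqrt((ax[, 1] - pr$x[i])^2 + (ax[, 2] - pr$y[i])^2))
    }, numeric(1))
    cpm_set_protected(state$ptr, as.integer(pr$sigma[which.min(rad)]), TRUE)
  }
  d
}

#' Run one scheduled mitosis round
#'
#' Selects the dividing LEP, divides each (skipping, with a warning, any
#' whose volume has dropped below 2 pixels), then rebuilds the spring
#' links.
#'
#' @param state a `cpm_state`.
#' @return A tibble of mitosis events (`mcs`, `event`, `sigma` of the new
#'   daughter, daughter center of mass).
#' @export
mitosis_round <- function(state) {
  sel <- select_mitotic_cells(state)
  out <- list()
  for (s in sel) {
    ag <- agents(state)
    row <- ag[ag$sigma == s, ]
    if (row$status != "active" || row$V < 2) {
      warn(sprintf("cell %s has volume below 2; division skipped", s))
      next
    }
    d <- divide_cell(state, s)
    if (!is.na(d)) out[[length(out) + 1L]] <- d
  }
  rebuild_links(state)
  if (!length(out)) return(empty_events())
  ds <- unlist(out)
  ag <- agents(state)
  dd <- ag[match(ds, ag$sigma), ]
  tibble::tibble(mcs = state$mcs, event = "mitosis", sigma = as.integer(ds),
                 x = dd$x, y = dd$y)
}

#' Crowding-gated apoptosis check
#'
#' For each live LEP, counts the other live LEP whose center of mass lies
#' within `crowding_radius` pixels (2.5 cell diameters by default; medium
#' and necrotic debris never count, and the myoepithelial sheath is not
#' part of the crowded luminal compartment). A LEP with
#' `crowding_threshold` or more such neighbours is overcrowded and, unless
#' protected, is removed with probability `apoptosis_prob`: its pixels
#' revert to medium immediately and its links retire.
#'
#' This is the same rule the simulation loop applies once per MCS; calling
#' it directly performs one check.
#'
#' @param state a `cpm_state`.
#' @return Integer vector of removed agent indices.
#' @export
apoptosis_check <- function(state) {
  p <- state$params
  cc <- cpm_crowding_counts(state$ptr, p$crowding_radius)
  if (nrow(cc) == 0) return(integer())
  ag <- agents(state)
  prot <- ag$sigma[ag$protected]
  over <- cc$sigma[cc$n_within >= p$crowding_threshold & !(cc$sigma %in% prot)]
  if (!length(over) || p$apoptosis_prob == 0) return(integer())
  doomed <- over[runif(length(over)) < p$apoptosis_prob]
  for (s in doomed) cpm_remove_agent(state$ptr, as.integer(s))
  if (length(doomed)) rebuild_links(state)
  as.integer(doomed)
}

#' Distance-gated necrosis check
#'
#' Any live LEP whose center of mass is `necrosis_dist` or more pixels
#' (inclusive) from the nearest MEP pixel turns necrotic: its type
#' changes, its adhesion and spring couplings to all partners drop to
#' zero, and its pixels remain as space-occupying debris. With no MEP
#' remaining the distances are undefined and the rule is skipped with a
#' warning.
#'
#' @param state a `cpm_state`.
#' @return Integer vector of newly necrotic agent indices.
#' @export
necrosis_check <- function(state) {
  ag <- agents(state)
  if (!any(ag$type == "MEP" & ag$status == "active")) {
    warn("no MEP remaining; necrosis rule skipped")
    return(integer())
  }
  cand <- cpm_necrosis_candidates(state$ptr, state$params$necrosis_dist)
  for (s in cand) cpm_set_type(state$ptr, as.integer(s), 3L)
  if (length(cand)) rebuild_links(state)
  as.integer(cand)
}
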