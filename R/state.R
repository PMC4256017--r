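#' Build a live simulation state from a duct tissue
#'
#' Wraps the compiled lattice engine. The state is a reference object (an
#' environment): engine operations mutate it in place. Spring links are
#' built at construction by one maintenance pass (see [rebuild_links()]).
#'
#' @param tissue a `duct_tissue` from [duct_circle()], [duct_cylinder()] or
#'   [duct_bifurcation()].
#' @param params a [cpm_params()] list.
#' @return An object of class `cpm_state`.
#' @examples
#' st <- cpm_state(duct_circle(), cpm_params())
#' nrow(agents(st))
#' @export
cpm_state <- function(tissue, params = cpm_params()) {
  stopifnot(inherits(tissue, "duct_tissue"), inherits(params, "cpm_params"))
  ag <- tissue$agents
  adf <- data.frame(
    sigma = ag$sigma,
    type = type_code(ag$type),
    Vt = ifelse(ag$type == "LEP", params$Vt_lep, params$Vt_mep),
    St = ifelse(ag$type == "LEP", params$St_lep, params$St_mep),
    lambda_V = ifelse(ag$type == "LEP", params$lambda_V_lep, params$lambda_V_mep),
    lambda_S = ifelse(ag$type == "LEP", params$lambda_S_lep, params$lambda_S_mep)
  )
  mats <- param_matrices(params)
  ptr <- cpm_create(tissue$lattice, adf, mats$J, mats$fpp_lambda, mats$fpp_L,
                    params$temperature, params$link_max_range)
  cpm_rebuild_links(ptr)
  st <- new.env(parent = emptyenv())
  st$ptr <- ptr
  st$geometry <- tissue$geometry
  st$params <- params
  st$mcs <- 0L
  class(st) <- "cpm_state"
  st
}

#' @export
print.cpm_state <- function(x, ...) {
  ag <- agents(x)
  live <- ag[ag$status == "active", ]
  cat(sprintf("<cpm_state> %s duct at MCS %d: %d LEP, %d MEP, %d necrotic\n",
              x$geometry$archetype, x$mcs,
              sum(live$type == "LEP"), sum(live$type == "MEP"),
              sum(live$type == "NECROTIC")))
  invisible(x)
}

#' Agent table of a simulation state or snapshot
#'
#' @param x a `cpm_state` or `dcis_snapshot`.
#' @return A tibble with one row per registered agent: index `sigma`, type,
#'   status (`active`, `annihilated`, `removed`), volume `V`, surface `S`,
#'   targets, stiffnesses, center of mass (`x`, `y`) and the
#'   apoptosis-protection flag.
#' @export
agents <- function(x) UseMethod("agents")

#' @export
agents.cpm_state <- function(x) {
  df <- cpm_agents(x$ptr)
  tibble::as_tibble(df) |>
    dplyr::mutate(
      type = type_label(.data$type),
      status = c("active", "annihilated", "removed")[.data$status],
      protected = as.logical(.data$protected)
    )
}

#' @export
agents.dcis_snapshot <- function(x) x$agents

#' Lattice raster of agent indices
#' @param x a `cpm_state` or `dcis_snapshot`.
#' @return An integer matrix (first dimension x, second y); 0 is medium.
#' @export
lattice <- function(x) UseMethod("lattice")

#' @export
lattice.cpm_state <- function(x) cpm_lattice(x$ptr)

#' @export
lattice.dcis_snapshot <- function(x) x$lattice

#' Spring links currently held between cells
#' @param x a `cpm_state`.
#' @return A tibble with endpoints `a`, `b`, spring constant `lambda`,
#'   target length `L` and current center-of-mass distance `length`.
#' @export
links <- function(x) UseMethod("links")

#' @export
links.cpm_state <- function(x) tibble::as_tibble(cpm_links(x$ptr))

#' Total effective energy of the configuration
#'
#' Sum of the contact-adhesion energy over neighbouring pixel pairs of
#' unequal index, the volume constraint `lambda_V (V - Vt)^2` and surface
#' constraint `lambda_S (S - St)^2` over cells, and the spring energy
#' `lambda_ij (l_ij - L_ij)^2` over links. A pure function of the state.
#'
#' @param state a `cpm_state`.
#' @return The energy (scalar).
#' @export
total_energy <- function(state) cpm_total_energy(state$ptr)

#' Exact energy change of a hypothetical pixel copy
#'
#' Returns the change in [total_energy()] if the pixel at `(x, y)` were
#' overwritten with agent index `source`, computed incrementally from the
#' local neighbourhood, the volume/surface deltas, and the affected spring
#' links. Does not modify the state; copying an identical index returns 0.
#'
#' @param state a `cpm_state`.
#' @param x,y 1-based pixel coordinates.
#' @param source agent index to copy in (0 for medium).
#' @return The energy change (scalar).
#' @export
delta_energy <- function(state, x, y, source) {
  cpm_delta_energy(state$ptr, as.integer(x), as.integer(y), as.integer(source))
}

#' Apply a single pixel copy unconditionally (bookkeeping included)
#' @inheritParams delta_energy
#' @return The state, invisibly.
#' @export
apply_copy <- function(state, x, y, source) {
  cpm_apply_copy(state$ptr, as.integer(x), as.integer(y), as.integer(source))
  invisible(state)
}

#' One Metropolis pixel-copy attempt
#'
#' Picks a random interior target pixel and a random one of its eight
#' neighbours as source; accepts with probability 1 if the energy change
#' is non-positive and `exp(-dH / T)` otherwise.
#'
#' @param state a `cpm_state`.
#' @return `TRUE` if the lattice changed.
#' @export
metropolis_attempt <- function(state) cpm_attempt(state$ptr) == 1L

#' Run Monte Carlo steps
#'
#' One Monte Carlo step (MCS) is one copy attempt per lattice pixel. With
#' `hooks = TRUE` the per-MCS biological checks run after each sweep:
#' crowding-gated apoptosis (each overcrowded, unprotected LEP is removed
#' with probability `apoptosis_prob`), then distance-gated necrosis (any
#' LEP at `necrosis_dist` or more from the nearest MEP pixel becomes
#' necrotic debris), with a link rebuild after any event. Mitosis is
#' scheduled by [simulate_duct()], not here.
#'
#' @param state a `cpm_state`.
#' @param n number of MCS (`n = 0` is the identity).
#' @param hooks run the per-MCS death checks?
#' @return A tibble of death events (columns `mcs`, `event`, `sigma`,
#'   `x`, `y`), invisibly empty when `hooks = FALSE`.
#' @export
run_mcs <- function(state, n, hooks = TRUE) {
  n <- as.integer(n)
  stopifnot(n >= 0)
  if (n == 0) return(invisible(empty_events()))
  p <- state$params
  if (!hooks) {
    cpm_sweep(state$ptr, n)
    state$mcs <- state$mcs + n
    return(invisible(empty_events()))
  }
  no_mep <- !any(agents(state)$type == "MEP" & agents(state)$status == "active")
  if (no_mep) warn("no MEP remaining; necrosis rule skipped")
  ev <- cpm_run_block(state$ptr, n, p$apoptosis_prob, p$crowding_radius,
                      p$crowding_threshold, p$necrosis_dist,
                      do_apoptosis = p$apoptosis_prob > 0,
                      do_necrosis = !no_mep, mcs_offset = state$mcs)
  state$mcs <- state$mcs + n
  invisible(event_tibble(ev))
}

empty_events <- function() {
  tibble::tibble(mcs = integer(), event = character(), sigma = integer(),
                 x = numeric(), y = numeric())
}

event_tibble <- function(ev) {
  tibble::tibble(mcs = as.integer(ev$mcs),
                 event = c("apoptosis", "necrosis", "mitosis")[ev$code],
                 sigma = as.integer(ev$sigma), x = ev$x, y = ev$y)
}

#' Maintain the spring-link sets
#'
#' Each live epithelial cell holds at most two links (polarity). Existing
#' links persist until an endpoint dies or turns necrotic or the
#' separation exceeds the capture range (`link_max_range`); cells with a
#' free link slot then bind their nearest unlinked epithelial neighbours
#' within range, closest pairs first. A link forms only when the pair's
#' contractile target length lies below the current separation, and never
#' to medium or necrotic debris. Maintenance is deterministic (ties break
#' on distance, then agent index) and runs once per MCS during
#' simulation; this function applies one maintenance pass.
#'
#' @param state a `cpm_state`.
#' @return The state, invisibly.
#' @export
rebuild_links <- function(state) {
  cpm_rebuild_links(state$ptr)
  invisible(state)
}

#' Freeze the current state into a plain snapshot
#'
#' @param state a `cpm_state`.
#' @return A `dcis_snapshot`: a list with the lattice raster, the agent
#'   tibble, the geometry metadata and the MCS clock. Snapshots are plain
#'   data and can be serialized, classified and plotted.
#' @export
snapshot <- function(state) {
  structure(
    list(lattice = lattice(state), agents = agents(state),
         geometry = state$geometry, mcs = state$mcs),
    class = "dcis_snapshot"
  )
}

#' @export
print.dcis_snapshot <- function(x, ...) {
  live <- x$agents[x$agents$status == "active", ]
  cat(sprintf("<dcis_snapshot> %s duct at MCS %d: %d LEP, %d MEP, %d necrotic\n",
              x$geometry$archetype, x$mcs,
              sum(live$type == "LEP"), sum(live$type == "MEP"),
              sum(live$type == "NECROTIC")))
  invisible(x)
}

# per-pixel type raster of a snapshot (codes 0..3)
type_raster <- function(snap) {
  lat <- snap$lattice
  tmap <- integer(max(lat) + 1L)
  tmap[snap$agents$sigma + 1L] <- type_code(snap$agents$type)
  out <- matrix(tmap[lat + 1L], nrow(lat), ncol(lat))
  out
}
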