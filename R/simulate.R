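#' Simulate DCIS development in a duct
#'
#' Runs the full model: Metropolis pixel-copy dynamics with the per-MCS
#' death checks, plus a mitosis round every `mitosis_interval` MCS in
#' which a quarter of the live LEP (resampled each round) divide along
#' the configured axis. With
#' `mitosis_interval = 50` and `n_mcs = 1000` this gives 20 mitotic
#' events; the 10-30 events per 1000 MCS of the standard sweeps
#' correspond to intervals between 100 and 33 MCS.
#'
#' @param tissue a `duct_tissue`, or one of `"circle"`, `"cylinder"`,
#'   `"bifurcation"` to build the default tissue of that archetype.
#' @param params a [cpm_params()] list.
#' @param n_mcs run length in Monte Carlo steps.
#' @param seed optional RNG seed for a reproducible trajectory.
#' @param checkpoint_every record a snapshot every this many MCS (`NULL`
#'   records only the final state).
#' @param relax_mcs bare relaxation MCS before the event layer starts
#'   (lets the seeded squares round up; 0 disables).
#' @return A `dcis_sim` object: list with the final `snapshot`, any
#'   checkpoint `snapshots` (named by MCS), the `events` tibble
#'   (mitosis / apoptosis / necrosis with MCS and position), `params` and
#'   `seed`.
#' @examples
#' \donttest{
#' sim <- simulate_duct("circle", cpm_params(), n_mcs = 100, seed = 1)
#' classify_morphology(sim$snapshot)
#' }
#' @export
simulate_duct <- function(tissue = "circle", params = cpm_params(),
                          n_mcs = 1000, seed = NULL, checkpoint_every = NULL,
                          relax_mcs = 0) {
  if (is.character(tissue))
    tissue <- switch(match.arg(tissue, c("circle", "cylinder", "bifurcation")),
                     circle = duct_circle(), cylinder = duct_cylinder(),
                     bifurcation = duct_bifurcation())
  if (!is.null(seed)) set.seed(seed)
  state <- cpm_state(tissue, params)
  if (relax_mcs > 0) run_mcs(state, relax_mcs, hooks = FALSE)
  state$mcs <- 0L
  events <- list()
  snaps <- list()
  # mitosis rounds fire at the start of each interval (MCS 0, i, 2i, ...),
  # so the last round's daughters integrate before the run ends
  mito <- seq(0L, n_mcs - 1L, by = params$mitosis_interval)
  chk <- if (is.null(checkpoint_every)) integer() else
    seq(checkpoint_every, n_mcs, by = checkpoint_every)
  marks <- sort(unique(c(mito, chk, n_mcs)))
  for (t in marks) {
    ev <- run_mcs(state, t - state$mcs, hooks = TRUE)
    if (nrow(ev)) events[[length(events) + 1L]] <- ev
    if (t %in% mito) {
      mv <- mitosis_round(state)
      if (nrow(mv)) events[[length(events) + 1L]] <- mv
    }
    if (t %in% chk) snaps[[as.character(t)]] <- snapshot(state)
  }
  structure(
    list(snapshot = snapshot(state), snapshots = snaps,
         events = if (length(events)) dplyr::bind_rows(events) else empty_events(),
         params = params, seed = seed, n_mcs = n_mcs,
         archetype = state$geometry$archetype),
    class = "dcis_sim"
  )
}

#' @export
print.dcis_sim <- function(x, ...) {
  cat(sprintf("<dcis_sim> %s duct, %d MCS, seed %s\n", x$archetype, x$n_mcs,
              x$seed %||% "unset"))
  print(x$snapshot)
  if (nrow(x$events))
    print(table(x$events$event))
  invisible(x)
}

#' @describeIn simulate_duct tidy method: the event log as a tibble.
#' @param x a `dcis_sim`.
#' @param ... unused.
#' @export
tidy.dcis_sim <- function(x, ...) x$events

#' @describeIn simulate_duct glance method: one-row run summary with final
#'   cell counts and the morphology verdict of the final snapshot.
#' @export
glance.dcis_sim <- function(x, ...) {
  ag <- x$snapshot$agents
  live <- ag[ag$status == "active", ]
  cls <- classify_morphology(x$snapshot)
  inv <- detect_invasion(x$snapshot)
  tibble::tibble(
    archetype = x$archetype, n_mcs = x$n_mcs, seed = x$seed %||% NA_integer_,
    n_lep = sum(live$type == "LEP"), n_mep = sum(live$type == "MEP"),
    n_necrotic = sum(live$type == "NECROTIC"),
    n_mitosis = sum(x$events$event == "mitosis"),
    n_apoptosis = sum(x$events$event == "apoptosis"),
    verdict = cls$verdict,
    end_invasion = inv$end_invasion, duct_invasion = inv$duct_invasion
  )
}
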