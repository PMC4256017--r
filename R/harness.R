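#' Run seeded replicate simulations of one condition
#'
#' Each replicate gets its own recorded seed derived from `base_seed`, and
#' rerunning a row's seed reproduces its verdict exactly. Snapshots at
#' every checkpoint are classified and scored for invasion.
#'
#' @param geometry `"circle"`, `"cylinder"`, `"bifurcation"`, or a
#'   `duct_tissue`.
#' @param params a [cpm_params()] list.
#' @param n_reps number of replicates.
#' @param n_mcs run length per replicate.
#' @param base_seed integer; replicate `i` runs with
#'   `base_seed + 7919 * i`.
#' @param checkpoint_every classify at every multiple of this many MCS in
#'   addition to the final state.
#' @param preset_name label stored in the results (provenance).
#' @return A tibble with one row per (replicate, checkpoint): condition
#'   descriptors, `replicate`, `seed`, `mcs`, the morphology verdict and
#'   evidence, and the invasion flags.
#' @export
run_replicates <- function(geometry = "circle", params = cpm_params(),
                           n_reps = 20, n_mcs = 1000, base_seed = 1,
                           checkpoint_every = NULL, preset_name = "default") {
  tissue <- if (is.character(geometry)) NULL else geometry
  gname <- if (is.character(geometry)) geometry else geometry$geometry$archetype
  rows <- lapply(seq_len(n_reps), function(i) {
    seed <- base_seed + 7919L * i
    sim <- simulate_duct(tissue %||% gname, params, n_mcs = n_mcs, seed = seed,
                         checkpoint_every = checkpoint_every)
    snaps <- c(sim$snapshots, list(final = sim$snapshot))
    mcss <- c(as.integer(names(sim$snapshots)), sim$n_mcs)
    keep <- !duplicated(mcss, fromLast = TRUE)
    purrr::map2(snaps[keep], mcss[keep], function(sn, m) {
      dplyr::bind_cols(
        tibble::tibble(geometry = gname, preset = preset_name,
                       apoptosis_prob = params$apoptosis_prob,
                       mitosis_interval = params$mitosis_interval,
                       n_events = length(seq(params$mitosis_interval, n_mcs,
                                             by = params$mitosis_interval)),
                       axis_mode = params$axis_mode,
                       replicate = i, seed = seed, mcs = m),
        classify_morphology(sn),
        detect_invasion(sn)[, c("end_invasion", "duct_invasion",
                                "n_invading", "breach_count")]
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Run a sweep over a grid of conditions
#'
#' @param grid a data frame of conditions; recognised columns (all
#'   optional) are `geometry`, `apoptosis_prob`, `n_events` (converted to
#'   `mitosis_interval = floor(n_mcs / n_events)`), `mitosis_interval`,
#'   `axis_mode`, `preset`, and any other [cpm_params()] name.
#' @param n_reps replicates per condition.
#' @param n_mcs run length.
#' @param base_seed base seed; each condition is offset so replicate seeds
#'   never collide across conditions.
#' @param checkpoint_every optional intermediate classification cadence.
#' @return A tibble of per-(condition, replicate, checkpoint) rows, as in
#'   [run_replicates()], plus a `condition` id column.
#' @export
run_sweep <- function(grid, n_reps = 20, n_mcs = 1000, base_seed = 1,
                      checkpoint_every = NULL) {
  grid <- tibble::as_tibble(grid)
  out <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    row <- as.list(grid[ci, ])
    geometry <- row$geometry %||% "circle"
    preset <- row$preset %||% "default"
    ov <- row[setdiff(names(row), c("geometry", "preset", "n_events"))]
    ov <- ov[!vapply(ov, is.null, logical(1))]
    if (!is.null(row$n_events))
      ov$mitosis_interval <- floor(n_mcs / row$n_events)
    params <- do.call(cpm_params, c(ov, list(preset = if (preset == "default")
      NULL else preset)))
    res <- tryCatch(
      run_replicates(geometry, params, n_reps = n_reps, n_mcs = n_mcs,
                     base_seed = base_seed + 1000003L * ci,
                     checkpoint_every = checkpoint_every,
                     preset_name = preset),
      error = function(e) {
        warn(sprintf("condition %d failed and was excluded: %s", ci,
                     conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) out[[ci]] <- dplyr::mutate(res, condition = ci,
                                                  .before = 1)
  }
  dplyr::bind_rows(out)
}

#' Consensus verdict per condition
#'
#' @param results a sweep/replicate results tibble.
#' @param at_mcs checkpoint to summarise (default: the last).
#' @param threshold consensus frequency (80% rule).
#' @return One row per condition with the consensus verdict and the
#'   verdict frequencies.
#' @export
sweep_consensus <- function(results, at_mcs = NULL, threshold = 0.8) {
  at_mcs <- at_mcs %||% max(results$mcs)
  results |>
    dplyr::filter(.data$mcs <= at_mcs) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c(
      "condition", "geometry", "preset", "apoptosis_prob", "n_events",
      "mitosis_interval", "axis_mode", "replicate")))) |>
    dplyr::slice_max(.data$mcs, n = 1) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c(
      "condition", "geometry", "preset", "apoptosis_prob", "n_events",
      "mitosis_interval", "axis_mode")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      consensus = consensus_verdict(.data$verdict, threshold),
      frac_micropapillary = mean(.data$verdict == "micropapillary"),
      frac_cribriform = mean(.data$verdict == "cribriform"),
      frac_solid = mean(.data$verdict == "solid"),
      frac_comedo = mean(.data$verdict == "comedo"),
      .groups = "drop"
    )
}

#' Fraction of replicates classified cribriform
#'
#' @param results replicate results (e.g. from [run_sweep()] over the
#'   parallel-axis, 1% apoptosis conditions).
#' @param at_mcs checkpoint MCS (classification uses the latest snapshot
#'   at or before it).
#' @return One row per condition: `n`, `n_cribriform`, `fraction`, and a
#'   95% binomial confidence band.
#' @export
cribriform_fraction <- function(results, at_mcs = 1000) {
  results |>
    dplyr::filter(.data$mcs <= at_mcs) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c(
      "condition", "geometry", "apoptosis_prob", "n_events",
      "mitosis_interval", "axis_mode", "replicate")))) |>
    dplyr::slice_max(.data$mcs, n = 1) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c(
      "condition", "geometry", "apoptosis_prob", "n_events",
      "mitosis_interval", "axis_mode")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_cribriform = sum(.data$verdict == "cribriform"),
      fraction = n_cribriform / n,
      ci_lo = stats::binom.test(n_cribriform, n)$conf.int[1],
      ci_hi = stats::binom.test(n_cribriform, n)$conf.int[2],
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::any_of("n_events")))
}

#' Morphology time courses and transitions across checkpoints
#'
#' @param results replicate results recorded with dense checkpoints.
#' @return A list with `courses` (one row per replicate: the ordered
#'   run-length-encoded verdict sequence) and `transitions` (counts of
#'   observed verdict-to-verdict transitions across all replicates).
#' @export
progression_course <- function(results) {
  courses <- results |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("condition", "replicate")))) |>
    dplyr::arrange(.data$mcs, .by_group = TRUE) |>
    dplyr::summarise(
      course = paste(rle(as.character(.data$verdict))$values, collapse = " -> "),
      final = dplyr::last(as.character(.data$verdict)),
      .groups = "drop"
    )
  trans <- results |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("condition", "replicate")))) |>
    dplyr::arrange(.data$mcs, .by_group = TRUE) |>
    dplyr::reframe(from = as.character(.data$verdict)[-dplyr::n()],
                   to = as.character(.data$verdict)[-1]) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::count(.data$from, .data$to)
  list(courses = courses, transitions = trans)
}

# does a course pass through the given stages in order (other stages may
# be interleaved)?
course_follows <- function(course, stages) {
  seq <- strsplit(course, " -> ", fixed = TRUE)[[1]]
  pos <- 0L
  for (s in stages) {
    hit <- which(seq == s)
    hit <- hit[hit > pos]
    if (!length(hit)) return(FALSE)
    pos <- hit[1]
  }
  TRUE
}

#' Per-region invasion frequencies
#'
#' @param results replicate results over cylinder / bifurcation runs.
#' @param at_mcs checkpoint MCS.
#' @return One row per condition: fractions of replicates with end-region
#'   and duct-region invasion.
#' @export
invasion_count <- function(results, at_mcs = NULL) {
  at_mcs <- at_mcs %||% max(results$mcs)
  results |>
    dplyr::filter(.data$mcs <= at_mcs) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c(
      "condition", "geometry", "preset", "apoptosis_prob",
      "mitosis_interval", "axis_mode", "replicate")))) |>
    dplyr::slice_max(.data$mcs, n = 1) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c(
      "condition", "geometry", "preset", "apoptosis_prob",
      "mitosis_interval", "axis_mode")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      end_fraction = mean(.data$end_invasion),
      duct_fraction = mean(.data$duct_invasion),
      .groups = "drop"
    )
}

#' Collapse a sweep onto the proliferation / apoptosis ratio
#'
#' Bins conditions by the ratio of mitotic events to apoptosis
#' probability; zero-apoptosis conditions go to the top (infinite-ratio)
#' bin. Verdict severity is ordered micropapillary < cribriform <
#' solid/comedo; across the printed sweeps the consensus severity rises
#' monotonically with the ratio.
#'
#' @param results a sweep results tibble covering an (events x apoptosis)
#'   grid.
#' @param at_mcs checkpoint MCS.
#' @return One row per ratio bin, ordered by increasing ratio, with the
#'   modal verdict and its severity rank.
#' @export
ratio_collapse <- function(results, at_mcs = NULL) {
  cons <- sweep_consensus(results, at_mcs = at_mcs)
  cons$ratio <- ifelse(cons$apoptosis_prob == 0, Inf,
                       cons$n_events / cons$apoptosis_prob)
  severity <- c(normal = 0, micropapillary = 1, cribriform = 2,
                solid = 3, comedo = 3, mixed = NA_real_)
  cons |>
    dplyr::group_by(.data$ratio) |>
    dplyr::summarise(
      n_conditions = dplyr::n(),
      verdict = consensus_verdict(.data$consensus, threshold = 0.5),
      .groups = "drop"
    ) |>
    dplyr::mutate(severity = unname(severity[.data$verdict])) |>
    dplyr::arrange(.data$ratio)
}
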