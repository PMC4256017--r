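# Mitosis selection and division geometry, apoptosis, necrosis.

test_that("a quarter of live LEP are selected, by the ceiling rule", {
  st <- cpm_state(duct_circle(), cpm_params(temperature = 6))
  set.seed(1)
  sel <- select_mitotic_cells(st)
  expect_length(sel, 13)                          # ceiling(0.25 * 50)
  expect_true(all(sel %in% agents(st)$sigma[agents(st)$type == "LEP"]))
  expect_equal(anyDuplicated(sel), 0)

  # no LEP alive -> empty selection
  lat <- matrix(0L, 30, 30); lat[10:19, 10:19] <- 1L
  st2 <- cpm_state(fixture_tissue(lat, "MEP"), cpm_params())
  expect_length(select_mitotic_cells(st2), 0)
})

test_that("selection is uniform without weighting and ~2x end-weighted with it", {
  st <- cpm_state(duct_cylinder(), cpm_params(temperature = 6))
  ag <- agents(st)
  lep <- ag[ag$type == "LEP", ]
  reg <- st$geometry$region
  in_end <- reg[cbind(round(lep$x), round(lep$y))] == 2L
  counts <- setNames(numeric(nrow(lep)), lep$sigma)
  set.seed(3)
  for (i in 1:4000) {
    sel <- select_mitotic_cells(st)
    counts[as.character(sel)] <- counts[as.character(sel)] + 1
  }
  k <- ceiling(0.25 * nrow(lep))
  expect_lt(max(abs(counts / 4000 - k / nrow(lep))), 0.05)  # uniform inclusion
  st$params$preferential_proliferation <- TRUE
  counts2 <- setNames(numeric(nrow(lep)), lep$sigma)
  for (i in 1:4000) {
    sel <- select_mitotic_cells(st)
    counts2[as.character(sel)] <- counts2[as.character(sel)] + 1
  }
  ratio <- mean(counts2[in_end]) / mean(counts2[!in_end])
  expect_equal(ratio, 2, tolerance = 0.1)         # "almost twice as frequently"
})

test_that("division bisects a square cell and conserves pixels", {
  lat <- matrix(0L, 30, 30); lat[11:20, 11:20] <- 1L
  st <- cpm_state(fixture_tissue(lat, "LEP"), cpm_params())
  d <- dcispotts:::cpm_divide(st$ptr, 1L, 0, 1)    # vertical cut
  ag <- agents(st)
  expect_equal(sort(ag$V), c(50, 50))
  expect_equal(sum(ag$V), 100)                     # partition, no pixel lost
  expect_equal(sum(lattice(st) == 1L) + sum(lattice(st) == d), 100)

  # any division conserves the parent volume exactly
  lat2 <- matrix(0L, 30, 30); lat2[11:20, 11:20] <- 1L
  st2 <- cpm_state(fixture_tissue(lat2, "LEP"), cpm_params())
  set.seed(9)
  d2 <- divide_cell(st2, 1L, axis_mode = "random")
  ag2 <- agents(st2)
  expect_equal(sum(ag2$V), 100)
})

test_that("perpendicular divisions keep daughters within the epithelial layer", {
  p <- cpm_params(temperature = 6)
  radial_offsets <- c(); tang_offsets <- c()
  set.seed(21)
  st <- cpm_state(duct_circle(), p)
  run_mcs(st, 10, hooks = FALSE)
  ctr <- st$geometry$center
  ag <- agents(st)
  lep <- ag$sigma[ag$type == "LEP" & ag$status == "active"]
  for (s in sample(lep, 30)) {
    before <- agents(st); pb <- before[before$sigma == s, ]
    d <- divide_cell(st, s, axis_mode = "perpendicular")
    after <- agents(st); da <- after[after$sigma == d, ]
    r0 <- sqrt((pb$x - ctr[1])^2 + (pb$y - ctr[2])^2)
    r1 <- sqrt((da$x - ctr[1])^2 + (da$y - ctr[2])^2)
    radial_offsets <- c(radial_offsets, abs(r1 - r0))
    ang <- abs(atan2(da$y - ctr[2], da$x - ctr[1]) -
               atan2(pb$y - ctr[2], pb$x - ctr[1]))
    tang_offsets <- c(tang_offsets, min(ang, 2 * pi - ang) * r0)
  }
  expect_lt(mean(radial_offsets), 5)               # within half a cell width
  expect_gt(mean(tang_offsets), mean(radial_offsets))
})

test_that("dividing a too-small cell is skipped with a warning", {
  lat <- matrix(0L, 20, 20); lat[10, 10] <- 1L
  st <- cpm_state(fixture_tissue(lat, "LEP"), cpm_params())
  expect_warning(d <- divide_cell(st, 1L), "skipped")
  expect_true(is.na(d))
})

test_that("crowding counts match a brute-force all-pairs oracle", {
  p <- cpm_params(temperature = 6)
  set.seed(14)
  st <- cpm_state(duct_circle(), p)
  run_mcs(st, 20, hooks = FALSE)
  suppressWarnings(mitosis_round(st))              # add some luminal daughters
  cc <- dcispotts:::cpm_crowding_counts(st$ptr, 25)
  ag <- agents(st)
  lep <- ag[ag$type == "LEP" & ag$status == "active", ]
  D <- as.matrix(stats::dist(lep[, c("x", "y")]))
  oracle <- rowSums(D <= 25) - 1L
  expect_equal(cc$n_within[match(lep$sigma, cc$sigma)], unname(oracle))
})

test_that("apoptosis never fires at probability zero and obeys the binomial rate", {
  p0 <- cpm_params(apoptosis_prob = 0)
  st <- cpm_state(duct_circle(), p0)
  set.seed(2)
  expect_length(apoptosis_check(st), 0)

  # 5x5 block of 25 contiguous LEP squares: every cell sees >= 10 within 25 px
  block <- function() {
    lat <- matrix(0L, 70, 70)
    s <- 0L
    for (i in 0:4) for (j in 0:4) {
      s <- s + 1L
      lat[10 + i * 10 + 1:10, 10 + j * 10 + 1:10] <- s
    }
    cpm_state(fixture_tissue(lat, rep("LEP", 25)),
              cpm_params(apoptosis_prob = 0.01))
  }
  set.seed(31)
  removed <- 0
  for (rep in 1:40) removed <- removed + length(apoptosis_check(block()))
  # 40 states x 25 overcrowded checks = 1000 Bernoulli(0.01) draws
  expect_gte(removed, 10 - 3 * sqrt(9.9))
  expect_lte(removed, 10 + 3 * sqrt(9.9))
})

test_that("apoptosis removal empties the cell and its links immediately", {
  lat <- matrix(0L, 40, 26)
  lat[6:15, 9:18] <- 1L; lat[16:25, 9:18] <- 2L
  st <- cpm_state(fixture_tissue(lat, c("LEP", "LEP")), cpm_params())
  expect_equal(nrow(links(st)), 1)
  dcispotts:::cpm_remove_agent(st$ptr, 1L)
  rebuild_links(st)
  expect_equal(sum(lattice(st) == 1L), 0)
  expect_equal(nrow(links(st)), 0)
  expect_equal(agents(st)$status[1], "removed")
})

test_that("necrosis triggers at 100 px inclusive, validated against brute force", {
  lat <- matrix(0L, 130, 30)
  lat[3:12, 11:20] <- 1L                           # MEP block
  lat[110, 15] <- 2L                               # LEP at distance just under 100
  lat[113, 15] <- 3L                               # LEP at distance > 100
  types <- c("MEP", "LEP", "LEP")
  st <- cpm_state(fixture_tissue(lat, types), cpm_params())
  dm <- dcispotts:::cpm_mep_distance(st$ptr)
  # brute-force oracle over every MEP pixel
  mep_px <- which(lat == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(dm))) {
    com <- agents(st)[agents(st)$sigma == dm$sigma[i], c("x", "y")]
    expect_equal(dm$dist_mep[i],
                 min(sqrt((mep_px[, 1] - com$x)^2 + (mep_px[, 2] - com$y)^2)))
  }
  nec <- necrosis_check(st)
  expect_true(3L %in% nec)
  expect_false(2L %in% nec)
  # exact boundary: place a LEP at exactly 100 px from the nearest MEP pixel
  lat2 <- matrix(0L, 130, 30)
  lat2[3:12, 11:20] <- 1L                          # nearest pixel x = 12, y = 15
  lat2[112, 15] <- 2L                              # distance exactly 100
  st2 <- cpm_state(fixture_tissue(lat2, c("MEP", "LEP")), cpm_params())
  expect_equal(dcispotts:::cpm_mep_distance(st2$ptr)$dist_mep, 100)
  expect_equal(necrosis_check(st2), 2L)            # >= 100 is inclusive
  ag <- agents(st2)
  expect_equal(ag$type[ag$sigma == 2], "NECROTIC")
  expect_equal(ag$V[ag$sigma == 2], 1)             # debris keeps its pixels
})

test_that("necrosis is skipped with a warning when no MEP remains", {
  lat <- matrix(0L, 30, 30); lat[10:19, 10:19] <- 1L
  st <- cpm_state(fixture_tissue(lat, "LEP"), cpm_params())
  expect_warning(out <- necrosis_check(st), "no MEP")
  expect_length(out, 0)
})

test_that("cell count changes only through division and apoptosis", {
  p <- cpm_params(temperature = 6, apoptosis_prob = 0.01, mitosis_interval = 25)
  sim <- suppressWarnings(simulate_duct("circle", p, n_mcs = 150, seed = 13))
  ag <- sim$snapshot$agents
  live <- sum(ag$status == "active" & ag$type %in% c("LEP", "MEP", "NECROTIC"))
  n_mit <- sum(sim$events$event == "mitosis")
  n_apo <- sum(sim$events$event == "apoptosis")
  expect_equal(live, 108 + n_mit - n_apo)          # 50 LEP + 58 MEP initially
})
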