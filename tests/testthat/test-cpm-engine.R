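# Energy terms, incremental delta-H bookkeeping, and the Metropolis rule.

test_that("total energy matches the brute-force oracle on hand-built fixtures", {
  p <- cpm_params(Vt_lep = 100, St_lep = 40, Vt_mep = 100, St_mep = 40)
  tis <- two_cell_tissue()
  st <- cpm_state(tis, p)
  # both 10x10 squares exactly at targets, one 10-face contact edge
  expect_equal(nrow(links(st)), 1)       # centers 10 apart, target 8
  lk <- links(st)
  expect_equal(lk$length, 10)
  expect_equal(lk$lambda, 50); expect_equal(lk$L, 8)
  E <- total_energy(st)
  expect_equal(E, -20 * 10 + 50 * (10 - 8)^2)   # frozen from the oracle below
  expect_equal(E, oracle_energy(lattice(st), tis$agents$type, p, links = lk))
})

test_that("a lone cell at its targets with no links has zero energy", {
  lat <- matrix(0L, 20, 20)
  lat[6:15, 6:15] <- 1L
  p <- cpm_params(Vt_lep = 100, St_lep = 40)
  st <- cpm_state(fixture_tissue(lat, "LEP"), p)
  expect_equal(total_energy(st), 0)
  expect_equal(nrow(links(st)), 0)
})

test_that("oracle and engine agree across random multi-cell fixtures", {
  for (seed in 1:5) {
    tis <- random_blob_tissue(seed)
    p <- cpm_params()
    st <- cpm_state(tis, p)
    expect_equal(total_energy(st),
                 oracle_energy(lattice(st), tis$agents$type, p, links = links(st)),
                 tolerance = 1e-12)
  }
})

test_that("copying an identical index changes nothing and costs nothing", {
  st <- cpm_state(two_cell_tissue(), cpm_params())
  expect_equal(delta_energy(st, 8, 12, lattice(st)[8, 12]), 0)
  before <- lattice(st)
  apply_copy(st, 8, 12, before[8, 12])
  expect_identical(lattice(st), before)
})

test_that("incremental delta-H equals the full energy difference", {
  set.seed(11)
  st <- cpm_state(random_blob_tissue(7), cpm_params())
  W <- nrow(lattice(st)); H <- ncol(lattice(st))
  for (i in 1:200) {
    x <- sample(2:(W - 1), 1); y <- sample(2:(H - 1), 1)
    k <- sample(8, 1)
    src <- lattice(st)[x + c(1, -1, 0, 0, 1, 1, -1, -1)[k],
                       y + c(0, 0, 1, -1, 1, -1, 1, -1)[k]]
    dH <- delta_energy(st, x, y, src)
    E0 <- total_energy(st)
    apply_copy(st, x, y, src)
    expect_equal(total_energy(st) - E0, dH, tolerance = 1e-9)
  }
})

test_that("annihilating a single-pixel cell includes the closed-form volume term", {
  lat <- matrix(0L, 15, 15)
  lat[8, 8] <- 1L
  p <- cpm_params()                      # lambda_V 5, Vt 78.5, St 31.4
  st <- cpm_state(fixture_tissue(lat, "LEP"), p)
  dH <- delta_energy(st, 8, 8, 0L)
  vol_term <- 5 * ((0 - 78.5)^2 - (1 - 78.5)^2)
  surf_term <- 1 * ((0 - 31.4)^2 - (4 - 31.4)^2)
  expect_equal(dH, vol_term + surf_term)
  E0 <- total_energy(st)
  apply_copy(st, 8, 8, 0L)
  expect_equal(total_energy(st) - E0, dH, tolerance = 1e-9)
  # retired: no pixels, and the index never reappears as a copy source
  expect_equal(sum(lattice(st) == 1L), 0)
  ag <- agents(st)
  expect_equal(ag$status[ag$sigma == 1], "annihilated")
})

test_that("the Metropolis acceptance rule has the right boundary behaviour", {
  set.seed(42)
  n <- 1e5
  expect_equal(dcispotts:::cpm_accept_sample(0, 6, n), n)      # dH = 0: always
  expect_equal(dcispotts:::cpm_accept_sample(-5, 6, n), n)     # downhill: always
  expect_equal(dcispotts:::cpm_accept_sample(5, 0, n), 0)      # T -> 0+: never uphill
  acc <- dcispotts:::cpm_accept_sample(6, 6, n) / n            # dH = T: exp(-1)
  expect_equal(acc, exp(-1), tolerance = 0.01 / exp(-1))
  acc_hot <- dcispotts:::cpm_accept_sample(5, 1e9, n) / n      # T -> Inf: ~1
  expect_gt(acc_hot, 0.999)
})

test_that("run_mcs(0) is the identity and occupancy is conserved", {
  st <- cpm_state(duct_circle(), cpm_params(temperature = 6))
  before <- lattice(st)
  run_mcs(st, 0)
  expect_identical(lattice(st), before)
  set.seed(1)
  run_mcs(st, 5, hooks = FALSE)
  ag <- agents(st)
  expect_equal(sum(ag$V), sum(lattice(st) > 0))   # bookkeeping identity
  sp <- split(seq_len(sum(lattice(st) > 0)), lattice(st)[lattice(st) > 0])
  expect_equal(sort(as.integer(names(sp))), sort(ag$sigma[ag$V > 0]))
})

test_that("identical seeds give bitwise-identical trajectories", {
  run_once <- function() {
    p <- cpm_params(temperature = 6, apoptosis_prob = 0.01, mitosis_interval = 30)
    sim <- suppressWarnings(simulate_duct("circle", p, n_mcs = 60, seed = 99))
    lattice(sim$snapshot)
  }
  expect_identical(run_once(), run_once())
})

test_that("cells stay essentially unfragmented under default parameters", {
  p <- cpm_params(temperature = 6)
  set.seed(8)
  st <- cpm_state(duct_circle(), p)
  run_mcs(st, 30, hooks = FALSE)
  cn <- dcispotts:::cpm_connectivity(st$ptr)
  expect_true(all(cn$largest_frac >= 0.9))
})

test_that("link maintenance respects polarity, range and the necrotic rule", {
  # three collinear LEP squares: middle links to both ends
  lat <- matrix(0L, 50, 26)
  lat[6:15, 9:18] <- 1L; lat[16:25, 9:18] <- 2L; lat[26:35, 9:18] <- 3L
  st <- cpm_state(fixture_tissue(lat, c("LEP", "LEP", "LEP")), cpm_params())
  lk <- links(st)
  deg <- table(factor(c(lk$a, lk$b), levels = 1:3))
  expect_equal(as.integer(deg[["2"]]), 2)
  expect_true(all(deg <= 2))
  expect_true(any((lk$a == 1 & lk$b == 2) | (lk$a == 2 & lk$b == 1)))
  expect_true(any((lk$a == 2 & lk$b == 3) | (lk$a == 3 & lk$b == 2)))

  # a lone cell holds no links
  lat2 <- matrix(0L, 30, 30)
  lat2[10:19, 10:19] <- 1L
  st2 <- cpm_state(fixture_tissue(lat2, "LEP"), cpm_params())
  expect_equal(nrow(links(st2)), 0)

  # necrotic partners never link
  lat3 <- matrix(0L, 40, 26)
  lat3[6:15, 9:18] <- 1L; lat3[16:25, 9:18] <- 2L
  st3 <- cpm_state(fixture_tissue(lat3, c("LEP", "LEP")), cpm_params())
  expect_equal(nrow(links(st3)), 1)
  dcispotts:::cpm_set_type(st3$ptr, 2L, 3L)      # becomes necrotic debris
  rebuild_links(st3)
  expect_equal(nrow(links(st3)), 0)
})

test_that("degree never exceeds two links per cell during a live run", {
  p <- cpm_params(temperature = 6, apoptosis_prob = 0.01, mitosis_interval = 25)
  sim <- suppressWarnings(simulate_duct("circle", p, n_mcs = 100, seed = 5))
  # re-open the final state indirectly: run a fresh short sim and inspect
  set.seed(5)
  st <- cpm_state(duct_circle(), p)
  run_mcs(st, 30)
  suppressWarnings(mitosis_round(st))
  lk <- links(st)
  expect_true(all(table(c(lk$a, lk$b)) <= 2))
})
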