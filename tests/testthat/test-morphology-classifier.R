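# Morphology fixtures are painted in code onto the circular duct geometry,
# then classified. Each morphology has several programmatic variants.

# paint extra LEP cells (10x10) into the lumen of the initial circle
circle_with_luminal <- function(fill = "none", n_tufts = 4, rot = 0,
                                necrotic_core = FALSE, bridge = FALSE,
                                holes = NULL) {
  tis <- duct_circle()
  lat <- tis$lattice
  types <- tis$agents$type
  g <- tis$geometry
  lum <- which(g$lumen0, arr.ind = TRUE)
  xr <- range(lum[, 1]); yr <- range(lum[, 2])
  nxt <- function() length(types) + 1L
  add_cell <- function(x0, y0, type) {
    s <- nxt()
    lat[x0:(x0 + 9), y0:(y0 + 9)] <<- s
    types <<- c(types, type)
    s
  }
  if (fill == "all") {
    for (x0 in seq(xr[1], xr[2] - 9, by = 10))
      for (y0 in seq(yr[1], yr[2] - 9, by = 10)) {
        inside <- g$lumen0[x0:(x0 + 9), y0:(y0 + 9)]
        if (all(inside)) add_cell(x0, y0, "LEP")
      }
    # paint any leftover lumen strip as extensions of the nearest new cells
    left <- which(g$lumen0 & lat == 0L, arr.ind = TRUE)
    if (nrow(left)) for (i in seq_len(nrow(left))) {
      x <- left[i, 1]; y <- left[i, 2]
      nb <- c(lat[max(x - 1, 1), y], lat[min(x + 1, nrow(lat)), y],
              lat[x, max(y - 1, 1)], lat[x, min(y + 1, ncol(lat))])
      nb <- nb[nb > 0]
      if (length(nb)) lat[x, y] <- nb[1]
    }
    if (!is.null(holes))
      for (h in holes) lat[h$x, h$y] <- 0L
    if (necrotic_core) {
      ctr <- g$center
      d <- sqrt((lum[, 1] - ctr[1])^2 + (lum[, 2] - ctr[2])^2)
      core <- unique(lat[lum[d < 25, , drop = FALSE]])
      core <- core[core > 50]                       # only painted luminal cells
      types[core] <- "NECROTIC"
    }
  } else if (fill == "tufts") {
    ctr <- g$center
    for (k in seq_len(n_tufts)) {
      th <- rot + 2 * pi * k / n_tufts
      x0 <- round(ctr[1] + 38 * cos(th)) ; y0 <- round(ctr[2] + 38 * sin(th))
      add_cell(x0, y0, "LEP")
    }
  }
  if (bridge) {
    # a straight column of LEP spanning the lumen through its center
    ctr <- round(g$center)
    ys <- seq(yr[1] - 2, yr[2] + 2, by = 10)
    for (y0 in ys) add_cell(ctr[1] + rot - 5, min(y0, ncol(lat) - 10), "LEP")
  }
  snapshot_from_lattice(lat, types, g)
}

test_that("the intact initial circle is classified normal", {
  tis <- duct_circle()
  sn <- snapshot_from_lattice(tis$lattice, tis$agents$type, tis$geometry)
  for (i in 1:2) expect_equal(as.character(classify_morphology(sn)$verdict), "normal")
})

test_that("luminal tufts with a patent lumen read micropapillary", {
  for (v in 1:5) {
    sn <- circle_with_luminal(fill = "tufts", n_tufts = 2 + v, rot = v / 3)
    cl <- classify_morphology(sn)
    expect_equal(as.character(cl$verdict), "micropapillary")
    expect_gte(cl$n_luminal_lep, 2)
    expect_equal(cl$n_necrotic, 0)
  }
})

test_that("a completely filled duct reads solid", {
  for (v in 1:5) {
    sn <- circle_with_luminal(fill = "all")
    cl <- classify_morphology(sn)
    expect_equal(as.character(cl$verdict), "solid")
    expect_equal(cl$n_lumena, 0)
    expect_lt(cl$lumen_area, pi * 25)
  }
})

test_that("a filled duct with interior necrotic debris reads comedo", {
  for (v in 1:5) {
    sn <- circle_with_luminal(fill = "all", necrotic_core = TRUE)
    cl <- classify_morphology(sn)
    expect_equal(as.character(cl$verdict), "comedo")
    expect_gt(cl$n_necrotic, 0)
  }
})

test_that("multiple lumena with a spanning bridge read cribriform", {
  g <- duct_circle()$geometry
  lum <- which(g$lumen0, arr.ind = TRUE)
  yr <- range(lum[, 2])
  for (v in 1:5) {
    holes <- list(
      list(x = 75:95, y = (60 + 2 * v):(80 + 2 * v)),
      list(x = 120:145, y = (120 - 2 * v):(145 - 2 * v))
    )
    sn <- circle_with_luminal(fill = "all", holes = holes)
    cl <- classify_morphology(sn)
    expect_equal(as.character(cl$verdict), "cribriform")
    expect_gte(cl$n_lumena, 2)
    expect_true(cl$bridge)
  }
})

test_that("lumen segmentation matches a flood-fill reading of the fixtures", {
  tis <- duct_circle()
  sn0 <- snapshot_from_lattice(tis$lattice, tis$agents$type, tis$geometry)
  expect_equal(nrow(segment_lumena(sn0)), 1)
  expect_equal(segment_lumena(sn0)$area, sum(tis$geometry$lumen0))
  sn_solid <- circle_with_luminal(fill = "all")
  expect_equal(nrow(segment_lumena(sn_solid)), 0)
  # an LEP bridge splitting the lumen -> 2 lumena
  sn_bridge <- circle_with_luminal(bridge = TRUE)
  expect_equal(nrow(segment_lumena(sn_bridge)), 2)
  # pockets under half a cell area are discarded as noise
  lat <- tis$lattice
  s <- nrow(tis$agents) + 1L
  lum <- which(tis$geometry$lumen0, arr.ind = TRUE)
  ctr <- round(tis$geometry$center)
  lat[(ctr[1] - 10):(ctr[1] + 10), (ctr[2] - 10):(ctr[2] + 10)] <- s
  lat[ctr[1] + (-2:2), ctr[2] + (-2:2)] <- 0L      # 25 px pocket < 50
  sn_pocket <- snapshot_from_lattice(lat, c(tis$agents$type, "LEP"), tis$geometry)
  expect_false(any(abs(segment_lumena(sn_pocket)$area - 25) < 1))
})

test_that("classification is a pure function of the snapshot", {
  sn <- circle_with_luminal(fill = "tufts", n_tufts = 5)
  expect_identical(classify_morphology(sn), classify_morphology(sn))
})

test_that("invasion requires LEP beyond the dilated initial periphery", {
  tis <- duct_circle()
  sn <- snapshot_from_lattice(tis$lattice, tis$agents$type, tis$geometry)
  inv <- detect_invasion(sn)
  expect_false(inv$end_invasion || inv$duct_invasion)
  expect_equal(inv$n_invading, 0)

  # plant a live LEP two cell diameters outside the MEP ring
  lat <- tis$lattice
  fp <- which(tis$geometry$tissue0, arr.ind = TRUE)
  x1 <- max(fp[, 1])
  yc <- round(mean(fp[, 2]))
  s <- nrow(tis$agents) + 1L
  lat[(x1 + 16):(x1 + 25), (yc - 5):(yc + 4)] <- s
  sn2 <- snapshot_from_lattice(lat, c(tis$agents$type, "LEP"), tis$geometry)
  inv2 <- detect_invasion(sn2)
  expect_true(inv2$duct_invasion)                  # circle is all duct region
  expect_false(inv2$end_invasion)
  expect_equal(inv2$n_invading, 1)
  expect_gte(inv2$breach_count, 0)
})

test_that("invaders at a cylinder tip are attributed to the end region", {
  tis <- duct_cylinder()
  g <- tis$geometry
  lat <- tis$lattice
  fp <- which(g$tissue0, arr.ind = TRUE)
  x1 <- max(fp[, 1]); yc <- round(mean(fp[, 2]))
  s <- nrow(tis$agents) + 1L
  lat[(x1 + 16):(x1 + 25), (yc - 5):(yc + 4)] <- s
  sn <- snapshot_from_lattice(lat, c(tis$agents$type, "LEP"), g)
  inv <- detect_invasion(sn)
  expect_true(inv$end_invasion)
  expect_false(inv$duct_invasion)
  # and one at the mid-duct wall goes to the duct region
  lat2 <- tis$lattice
  xc <- round(mean(fp[, 1])); y1 <- max(fp[, 2])
  lat2[(xc - 5):(xc + 4), (y1 + 16):(y1 + 25)] <- s
  sn2 <- snapshot_from_lattice(lat2, c(tis$agents$type, "LEP"), g)
  inv2 <- detect_invasion(sn2)
  expect_true(inv2$duct_invasion)
  expect_false(inv2$end_invasion)
})

test_that("consensus follows the 80% rule", {
  expect_equal(consensus_verdict(rep(c("micropapillary", "solid"), c(16, 4))),
               "micropapillary")
  expect_equal(consensus_verdict(rep(c("solid", "comedo"), c(10, 10))), "mixed")
  expect_equal(consensus_verdict(rep("cribriform", 20)), "cribriform")
  expect_equal(consensus_verdict("normal"), "normal")
})
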