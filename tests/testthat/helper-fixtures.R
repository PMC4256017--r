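# Hand-built lattice fixtures and an independent brute-force energy oracle.
# The oracle recomputes every energy term from the raw lattice with plain R
# vector arithmetic; it shares no code with the engine's incremental
# bookkeeping.

TYPES4 <- c("MEDIUM", "LEP", "MEP", "NECROTIC")

fixture_geometry <- function(W, H, cell_px = 10) {
  list(archetype = "fixture", cell_px = cell_px, end_depth = NA,
       lumen_halfwidth = W / 4,
       center = c(W / 2, H / 2),
       lumen0 = matrix(FALSE, W, H), tissue0 = matrix(FALSE, W, H),
       mep0 = matrix(FALSE, W, H),
       region = matrix(0L, W, H),
       axis = matrix(c(W / 2, H / 2), 1, 2),
       dist_to_tissue0 = matrix(0, W, H), dist_in_lumen0 = matrix(0, W, H))
}

# wrap a painted lattice as a duct_tissue so cpm_state() accepts it
fixture_tissue <- function(lat, types, cell_px = 10) {
  structure(
    list(lattice = lat,
         agents = tibble::tibble(sigma = seq_along(types), type = types),
         geometry = fixture_geometry(nrow(lat), ncol(lat), cell_px)),
    class = "duct_tissue")
}

# two 10x10 cells side by side on a small lattice, 10-pixel contact edge
two_cell_tissue <- function(types = c("LEP", "LEP"), W = 40, H = 30) {
  lat <- matrix(0L, W, H)
  lat[6:15, 11:20] <- 1L
  lat[16:25, 11:20] <- 2L
  fixture_tissue(lat, types)
}

# scatter k random compact cells on a lattice no larger than 30x30
random_blob_tissue <- function(seed, k = 4, W = 30, H = 30) {
  set.seed(seed)
  lat <- matrix(0L, W, H)
  for (s in seq_len(k)) {
    cx <- sample(6:(W - 5), 1); cy <- sample(6:(H - 5), 1)
    x <- cx; y <- cy
    for (i in 1:40) {              # biased random walk paints a blob
      if (x > 2 && x < W - 1 && y > 2 && y < H - 1 && lat[x, y] == 0L)
        lat[x, y] <- s
      st <- sample(4, 1)
      x <- x + c(1, -1, 0, 0)[st]; y <- y + c(0, 0, 1, -1)[st]
      if (runif(1) < 0.35) { x <- cx; y <- cy }   # re-center: keeps it compact
    }
    if (!any(lat == s)) lat[cx, cy] <- s
  }
  keep <- sort(unique(lat[lat > 0]))
  lat2 <- matrix(0L, W, H)
  for (i in seq_along(keep)) lat2[lat == keep[i]] <- i
  fixture_tissue(lat2, rep(c("LEP", "MEP"), length.out = length(keep)))
}

# brute-force total energy from the lattice alone
oracle_energy <- function(lat, agents_types, params, links = NULL) {
  W <- nrow(lat); H <- ncol(lat)
  J <- matrix(0, 4, 4)
  J[2, 2] <- params$J_lep_lep
  J[2, 3] <- J[3, 2] <- params$J_lep_mep
  J[3, 3] <- params$J_mep_mep
  tmap <- integer(max(lat) + 2L)
  tmap[seq_along(agents_types) + 1L] <- match(agents_types, TYPES4) - 1L
  ty <- matrix(tmap[lat + 1L], W, H)
  E <- 0
  for (o in list(c(1, 0), c(0, 1))) {
    x1 <- 1:(W - 1); y1 <- if (o[2] >= 0) 1:(H - o[2]) else 2:H
    if (o[1] == 0) x1 <- 1:W
    x2 <- x1 + o[1]; y2 <- y1 + o[2]
    a <- lat[x1, y1]; b <- lat[x2, y2]
    E <- E + sum(J[cbind(as.vector(ty[x1, y1]) + 1L,
                         as.vector(ty[x2, y2]) + 1L)] * as.vector(a != b))
  }
  for (s in seq_along(agents_types)) {
    V <- sum(lat == s)
    if (V == 0) next                       # rule-removed agents contribute 0
    S <- face_count(lat, s)
    lep <- agents_types[s] == "LEP"
    lamV <- if (lep) params$lambda_V_lep else params$lambda_V_mep
    lamS <- if (lep) params$lambda_S_lep else params$lambda_S_mep
    Vt <- if (lep) params$Vt_lep else params$Vt_mep
    St <- if (lep) params$St_lep else params$St_mep
    E <- E + lamV * (V - Vt)^2 + lamS * (S - St)^2
  }
  if (!is.null(links) && nrow(links)) {
    com <- cell_coms(lat)
    for (i in seq_len(nrow(links))) {
      a <- links$a[i]; b <- links$b[i]
      l <- sqrt(sum((com[com$sigma == a, c("x", "y")] -
                     com[com$sigma == b, c("x", "y")])^2))
      E <- E + links$lambda[i] * (l - links$L[i])^2
    }
  }
  E
}

face_count <- function(lat, s) {
  W <- nrow(lat); H <- ncol(lat)
  pad <- matrix(-1L, W + 2, H + 2)
  pad[2:(W + 1), 2:(H + 1)] <- lat
  mask <- pad == s
  sum(mask[2:(W + 1), 2:(H + 1)] & pad[1:W, 2:(H + 1)] != s) +
    sum(mask[2:(W + 1), 2:(H + 1)] & pad[3:(W + 2), 2:(H + 1)] != s) +
    sum(mask[2:(W + 1), 2:(H + 1)] & pad[2:(W + 1), 1:H] != s) +
    sum(mask[2:(W + 1), 2:(H + 1)] & pad[2:(W + 1), 3:(H + 2)] != s)
}

cell_coms <- function(lat) {
  idx <- which(lat > 0)
  xs <- ((idx - 1) %% nrow(lat)) + 1
  ys <- ((idx - 1) %/% nrow(lat)) + 1
  sig <- lat[idx]
  data.frame(sigma = as.integer(names(tapply(xs, sig, mean))),
             x = as.numeric(tapply(xs, sig, mean)),
             y = as.numeric(tapply(ys, sig, mean)))
}

# snapshot built straight from a painted lattice (no engine involved)
snapshot_from_lattice <- function(lat, types, geometry, mcs = 0L) {
  com <- cell_coms(lat)
  sig <- sort(unique(lat[lat > 0]))
  Vtab <- table(lat[lat > 0])
  agents <- tibble::tibble(
    sigma = sig,
    type = types[sig],
    status = "active",
    V = as.numeric(Vtab[as.character(sig)]),
    S = NA_real_, Vt = NA_real_, St = NA_real_,
    lambda_V = NA_real_, lambda_S = NA_real_,
    x = com$x[match(sig, com$sigma)], y = com$y[match(sig, com$sigma)],
    protected = FALSE)
  structure(list(lattice = lat, agents = agents, geometry = geometry,
                 mcs = mcs), class = "dcis_snapshot")
}

# moment-based circularity: 1 for a disk, ~0.955 for a solid square
moment_circularity <- function(lat) {
  idx <- which(lat > 0)
  xs <- ((idx - 1) %% nrow(lat)) + 1
  ys <- ((idx - 1) %/% nrow(lat)) + 1
  sig <- lat[idx]
  vapply(split(seq_along(sig), sig), function(i) {
    mx <- mean(xs[i]); my <- mean(ys[i])
    r2 <- mean((xs[i] - mx)^2 + (ys[i] - my)^2) + 1 / 6  # pixel-center correction
    length(i) / (2 * pi * r2)
  }, numeric(1))
}
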