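#' Duct tissue archetypes
#'
#' Construct the initial lattice and agent table for the three tissue
#' archetypes: the circular cross-section of a mammary duct, the
#' longitudinal section of a cylindrical duct, and a bifurcating (Y-shaped)
#' duct. All three produce a closed myoepithelial (MEP) monolayer enclosing
#' a closed luminal epithelial (LEP) monolayer enclosing a medium lumen,
#' with culture medium outside. Cells are seeded as squares (or compact
#' pixel clusters for the bifurcation) and round up within a few MCS under
#' the surface and volume constraints.
#'
#' `duct_circle()` builds the cross-section as a closed rectangular ring of
#' exactly `n_lep` 10x10-pixel LEP squares enclosed by a ring of MEP
#' squares; under the contractile spring links the ring relaxes toward a
#' rounded annulus. `duct_cylinder()` builds a longitudinal section: two
#' parallel LEP walls capped at both tips, the MEP layer outside, and a
#' lumen strip inside. `duct_bifurcation()` builds one trunk and two
#' branches at `branch_angle` degrees, with the same layering; its cells
#' are compact clusters of about 100 pixels obtained by k-means
#' partitioning of the monolayer bands.
#'
#' The returned geometry metadata fixes, at MCS 0: the lumen and tissue
#' footprints, the medial axis used to orient division axes, and the
#' end/duct region partition used for invasion attribution (`end` covers
#' each tip to a depth of `end_depth` pixels; the circle is all `duct`).
#'
#' @param n_lep number of LEP cells in the circular monolayer (must give an
#'   even perimeter: `(n_lep + 4) / 2` integer).
#' @param cell_px nominal cell diameter in pixels (1 px = 1 micron).
#' @param margin medium margin around the tissue, pixels.
#' @param lumen_width lumen strip width, pixels.
#' @param duct_length cylinder lumen length, pixels (multiple of `cell_px`).
#' @param trunk_length,branch_length centerline lengths, pixels.
#' @param branch_angle branch half-angle from the trunk axis, degrees.
#' @param end_depth depth of the end regions measured along the duct from
#'   each free tip, pixels; defaults to one initial lumen diameter.
#' @return A `duct_tissue`: list with the integer `lattice` (0 = medium),
#'   the `agents` tibble (`sigma`, `type`), and `geometry` metadata.
#' @examples
#' tis <- duct_circle()
#' table(tis$agents$type)
#' @export
duct_circle <- function(n_lep = 50, cell_px = 10, margin = 35) {
  s <- (n_lep + 4) / 2
  if (s != round(s)) abort("n_lep must make (n_lep + 4) / 2 an integer")
  a <- floor(s / 2); b <- s - a           # LEP ring grid, cells (13 x 14 for 50)
  build_rect_ring(a, b, cell_px, margin, archetype = "circle", end_depth = NA)
}

#' @rdname duct_circle
#' @export
duct_cylinder <- function(lumen_width = 50, duct_length = 300, cell_px = 10,
                          end_depth = lumen_width, margin = 35) {
  lc <- duct_length / cell_px; wc <- lumen_width / cell_px
  if (lc != round(lc) || wc != round(wc))
    abort("duct_length and lumen_width must be multiples of cell_px")
  build_rect_ring(lc + 2, wc + 2, cell_px, margin, archetype = "cylinder",
                  end_depth = end_depth)
}

# closed rectangular ring: LEP ring grid a x b cells, MEP ring around it,
# lumen = inner (a-2) x (b-2) cells of medium
build_rect_ring <- function(a, b, cell_px, margin, archetype, end_depth) {
  if (a < 3 || b < 3) abort("tissue too small: monolayer ring needs >= 3 cells per side")
  A <- a + 2; B <- b + 2                  # MEP ring grid
  W <- A * cell_px + 2 * margin
  H <- B * cell_px + 2 * margin
  if (margin < cell_px + 2) abort("margin too small for the medium frame")
  lat <- matrix(0L, W, H)
  lep <- matrix(FALSE, W, H); mep <- matrix(FALSE, W, H); lum <- matrix(FALSE, W, H)
  sig <- 0L
  agents <- list()
  place <- function(i, j) {                # cell (i, j) of the MEP grid, px range
    list(x = margin + (i - 1) * cell_px + seq_len(cell_px),
         y = margin + (j - 1) * cell_px + seq_len(cell_px))
  }
  # LEP ring first so sigma 1..n_lep are LEP
  for (i in seq_len(A)) for (j in seq_len(B)) {
    on_mep <- i == 1 || i == A || j == 1 || j == B
    ii <- i - 1; jj <- j - 1                # position in LEP grid
    on_lep <- !on_mep && (ii == 1 || ii == a || jj == 1 || jj == b)
    if (!on_lep) next
    sig <- sig + 1L
    p <- place(i, j)
    lat[p$x, p$y] <- sig
    lep[p$x, p$y] <- TRUE
    agents[[sig]] <- c(sig, 1L)
  }
  for (i in seq_len(A)) for (j in seq_len(B)) {
    if (!(i == 1 || i == A || j == 1 || j == B)) next
    sig <- sig + 1L
    p <- place(i, j)
    lat[p$x, p$y] <- sig
    mep[p$x, p$y] <- TRUE
    agents[[sig]] <- c(sig, 2L)
  }
  for (i in seq_len(A)) for (j in seq_len(B)) {
    ii <- i - 1; jj <- j - 1
    in_lumen <- ii >= 2 && ii <= a - 1 && jj >= 2 && jj <= b - 1
    if (in_lumen) { p <- place(i, j); lum[p$x, p$y] <- TRUE }
  }
  am <- do.call(rbind, agents)
  agents <- tibble::tibble(sigma = as.integer(am[, 1]),
                           type = type_label(am[, 2]))
  cx <- mean(which(rowSums(lum) > 0)); cy <- mean(which(colSums(lum) > 0))
  if (archetype == "circle") {
    axis <- matrix(c(cx, cy), 1, 2)
    region <- matrix(0L, W, H); region[lep | mep | lum] <- 1L
  } else {
    x0 <- margin + cell_px * 2 + 0.5      # lumen x-range endpoints
    x1 <- margin + (A - 2) * cell_px + 0.5
    axis <- cbind(seq(x0, x1, by = 1), cy)
    region <- matrix(0L, W, H)
    fp <- lep | mep | lum
    region[fp] <- 1L
    px <- row(lat)
    tx <- range(px[fp])
    ends <- fp & (px <= tx[1] + end_depth | px >= tx[2] - end_depth)
    region[ends] <- 2L
  }
  new_duct_tissue(lat, agents, archetype, lep, mep, lum, region, axis,
                  cell_px, end_depth, lumen_halfwidth = if (archetype == "circle")
                    sqrt(sum(lum) / pi) else (b - 2) * cell_px / 2)
}

#' @rdname duct_circle
#' @export
duct_bifurcation <- function(lumen_width = 50, trunk_length = 150,
                             branch_length = 150, branch_angle = 45,
                             cell_px = 10, end_depth = lumen_width,
                             margin = 35) {
  half <- lumen_width / 2
  th <- branch_angle * pi / 180
  # centerline segments in local coordinates
  P0 <- c(0, 0); PJ <- c(trunk_length, 0)
  B1 <- PJ + branch_length * c(cos(th), sin(th))
  B2 <- PJ + branch_length * c(cos(th), -sin(th))
  segs <- list(rbind(P0, PJ), rbind(PJ, B1), rbind(PJ, B2))
  pad <- half + 2 * cell_px
  xr <- range(0, trunk_length, B1[1], B2[1]) + c(-pad, pad)
  yr <- range(0, B1[2], B2[2]) + c(-pad, pad)
  W <- ceiling(diff(xr)) + 2 * margin
  H <- ceiling(diff(yr)) + 2 * margin
  ox <- margin - xr[1]; oy <- margin - yr[1]   # local -> lattice offset
  px <- row(matrix(0, W, H)) - ox
  py <- col(matrix(0, W, H)) - oy
  dmat <- array(Inf, dim = c(W, H))
  along <- array(Inf, dim = c(W, H))           # arclength distance to free tip
  for (k in seq_along(segs)) {
    sg <- segs[[k]]
    vx <- sg[2, 1] - sg[1, 1]; vy <- sg[2, 2] - sg[1, 2]
    len2 <- vx^2 + vy^2
    t <- pmin(pmax(((px - sg[1, 1]) * vx + (py - sg[1, 2]) * vy) / len2, 0), 1)
    d <- sqrt((px - (sg[1, 1] + t * vx))^2 + (py - (sg[1, 2] + t * vy))^2)
    # free tips: trunk start (t = 0), branch ends (t = 1)
    tipdist <- if (k == 1) t * sqrt(len2) else (1 - t) * sqrt(len2)
    upd <- d < dmat
    along[upd] <- tipdist[upd]
    dmat[upd] <- d[upd]
  }
  lum <- dmat <= half
  lepb <- dmat > half & dmat <= half + cell_px
  mepb <- dmat > half + cell_px & dmat <= half + 2 * cell_px
  lat <- matrix(0L, W, H)
  seed_cells <- function(mask, first_sigma) {
    coords <- cbind(px[mask] , py[mask])
    k <- max(1L, round(nrow(coords) / (cell_px^2)))
    ord <- order(coords[, 1], coords[, 2])
    init <- coords[ord[round(seq(1, nrow(coords), length.out = k))], , drop = FALSE]
    km <- suppressWarnings(kmeans(coords, centers = init, iter.max = 100))
    lat[mask] <<- first_sigma + km$cluster - 1L
    k
  }
  n_lep <- seed_cells(lepb, 1L)
  n_mep <- seed_cells(mepb, n_lep + 1L)
  agents <- tibble::tibble(
    sigma = seq_len(n_lep + n_mep),
    type = rep(c("LEP", "MEP"), c(n_lep, n_mep))
  )
  fp <- lepb | mepb
  region <- matrix(0L, W, H)
  region[fp | lum] <- 1L
  region[(fp | lum) & along <= end_depth] <- 2L
  axis <- do.call(rbind, lapply(segs, function(sg) {
    n <- ceiling(sqrt(sum((sg[2, ] - sg[1, ])^2)))
    cbind(seq(sg[1, 1], sg[2, 1], length.out = n) + ox,
          seq(sg[1, 2], sg[2, 2], length.out = n) + oy)
  }))
  new_duct_tissue(lat, agents, "bifurcation", lepb, mepb, lum, region, axis,
                  cell_px, end_depth, lumen_halfwidth = half)
}

new_duct_tissue <- function(lat, agents, archetype, lep0, mep0, lumen0,
                            region, axis, cell_px, end_depth, lumen_halfwidth) {
  tissue0 <- lep0 | mep0
  # distance of every pixel to the tissue footprint (0 on the footprint)
  dist_to_tissue0 <- as.matrix(EBImage::distmap(EBImage::Image(1 - tissue0)))
  # depth inside the initial lumen (0 outside it)
  dist_in_lumen0 <- as.matrix(EBImage::distmap(EBImage::Image(lumen0 * 1)))
  geometry <- list(
    archetype = archetype, cell_px = cell_px, end_depth = end_depth,
    lumen_halfwidth = lumen_halfwidth,
    center = c(mean(row(lat)[lumen0]), mean(col(lat)[lumen0])),
    lumen0 = lumen0, tissue0 = tissue0, mep0 = mep0,
    region = region, axis = axis,
    dist_to_tissue0 = dist_to_tissue0, dist_in_lumen0 = dist_in_lumen0
  )
  structure(list(lattice = lat, agents = agents, geometry = geometry),
            class = "duct_tissue")
}

#' @export
print.duct_tissue <- function(x, ...) {
  cat(sprintf("<duct_tissue> %s: %d LEP + %d MEP on a %d x %d lattice\n",
              x$geometry$archetype, sum(x$agents$type == "LEP"),
              sum(x$agents$type == "MEP"), nrow(x$lattice), ncol(x$lattice)))
  invisible(x)
}

# nearest medial-axis point and unit radial direction at a point
layer_direction <- function(geometry, x, y) {
  ax <- geometry$axis
  i <- which.min((ax[, 1] - x)^2 + (ax[, 2] - y)^2)
  r <- unname(c(x - ax[i, 1], y - ax[i, 2]))
  n <- sqrt(sum(r^2))
  if (n < 1e-9) r <- c(1, 0) else r <- r / n
  list(radial = r, tangential = c(-r[2], r[1]))
}

# region label ("end"/"duct") of the nearest initial-footprint point
nearest_region <- function(geometry, x, y) {
  fp <- which(geometry$tissue0, arr.ind = TRUE)
  i <- which.min((fp[, 1] - x)^2 + (fp[, 2] - y)^2)
  if (geometry$region[fp[i, 1], fp[i, 2]] == 2L) "end" else "duct"
}
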