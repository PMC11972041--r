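#' Voxel grid specification
#'
#' @param origin Length-3 lower corner of the grid (mm, room frame).
#' @param voxel_size Length-3 voxel edge lengths, mm; default 8 x 8 x 10
#'   (the z size sets the slice thickness along the beam axis).
#' @param shape Length-3 integer voxel counts per axis.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(origin = c(-40, -40, -80), voxel_size = c(8, 8, 10),
                      shape = c(10, 10, 16)) {
  stopifnot(length(origin) == 3, length(voxel_size) == 3, length(shape) == 3,
            all(voxel_size > 0), all(shape >= 1))
  structure(list(origin = as.numeric(origin),
                 voxel_size = as.numeric(voxel_size),
                 shape = as.integer(shape)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels of %g x %g x %g mm from (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel center coordinates along one axis
#' @param grid A [grid_spec].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of voxel centers, mm.
#' @export
grid_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$voxel_size[axis]
}

#' Voxelize a vertex collection into a fragment distribution
#'
#' Counts reconstructed fragmentation vertices in the voxels of `grid`.
#' Voxel intervals are half-open, `[edge, edge + size)`, so a vertex exactly
#' on an interior edge is assigned to the higher voxel. Vertices outside the
#' grid are tallied separately; in-grid plus outside always equals the input
#' count.
#'
#' @param vertices `data.frame` with columns `x`, `y`, `z` (mm).
#' @param grid A [grid_spec].
#' @return Object of class `fragment_distribution`: `grid`, integer `counts`
#'   array of dimension `grid$shape`, `n_total_in_grid`, `n_outside`.
#' @export
voxelize <- function(vertices, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ix <- floor((vertices$x - grid$origin[1]) / grid$voxel_size[1])
  iy <- floor((vertices$y - grid$origin[2]) / grid$voxel_size[2])
  iz <- floor((vertices$z - grid$origin[3]) / grid$voxel_size[3])
  inside <- ix >= 0 & ix < grid$shape[1] &
            iy >= 0 & iy < grid$shape[2] &
            iz >= 0 & iz < grid$shape[3]
  counts <- array(0L, dim = grid$shape)
  if (any(inside)) {
    lin <- 1L + ix[inside] + grid$shape[1] * (iy[inside] + grid$shape[2] * iz[inside])
    tab <- tabulate(lin, nbins = prod(grid$shape))
    counts[] <- tab
  }
  structure(list(grid = grid, counts = counts,
                 n_total_in_grid = sum(inside),
                 n_outside = sum(!inside)),
            class = "fragment_distribution")
}

#' @export
print.fragment_distribution <- function(x, ...) {
  cat(sprintf("<fragment_distribution> %d vertices in grid (+%d outside), max voxel %d\n",
              x$n_total_in_grid, x$n_outside, max(x$counts)))
  print(x$grid)
  invisible(x)
}

## literal significance rule: |N2 - N1| >= k * sqrt(N1 + N2)
.poisson_significant <- function(n1, n2, k_sigma) {
  abs(n2 - n1) >= k_sigma * sqrt(n1 + n2)
}

#' Difference map between two fragment distributions
#'
#' Computes the per-voxel count difference `N2 - N1` and marks voxels whose
#' difference exceeds the Poisson significance threshold
#' `|N2 - N1| >= k_sigma * sqrt(N1 + N2)` (at the default `k_sigma = 2` this
#' demands a difference beyond the 95.4% confidence level of the combined
#' counting uncertainty). Only voxels above a minimum count are eligible —
#' sparsely populated voxels are dominated by counting noise and are excluded
#' before thresholding, mirroring the visualization threshold used on the
#' distribution maps.
#'
#' @param d1,d2 `fragment_distribution`s on the identical grid.
#' @param min_count Eligibility threshold: a voxel must exceed this count
#'   (default 100).
#' @param k_sigma Significance threshold in Poisson sigma (default 2).
#' @param eligibility `"both"` (default) requires `N1 > min_count` and
#'   `N2 > min_count`; `"either"` requires at least one; `"first"` only `N1`.
#' @return Object of class `difference_map`: `grid`, `n1`, `n2`, `delta`
#'   (= `n2 - n1`), logical arrays `eligible` and `significant`
#'   (`significant` implies `eligible`), plus the thresholds used.
#' @export
difference_map <- function(d1, d2, min_count = 100, k_sigma = 2,
                           eligibility = c("both", "either", "first")) {
  stopifnot(inherits(d1, "fragment_distribution"),
            inherits(d2, "fragment_distribution"))
  eligibility <- match.arg(eligibility)
  if (!isTRUE(all.equal(d1$grid, d2$grid))) {
    stop("difference_map requires identical grids")
  }
  n1 <- d1$counts; n2 <- d2$counts
  eligible <- switch(eligibility,
                     both = n1 > min_count & n2 > min_count,
                     either = n1 > min_count | n2 > min_count,
                     first = n1 > min_count)
  significant <- eligible & .poisson_significant(n1, n2, k_sigma)
  structure(list(grid = d1$grid, n1 = n1, n2 = n2, delta = n2 - n1,
                 eligible = eligible, significant = significant,
                 min_count = min_count, k_sigma = k_sigma,
                 eligibility = eligibility),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat(sprintf("<difference_map> %d eligible voxels (>%d counts, %s), %d significant at %g sigma\n",
              sum(x$eligible), x$min_count, x$eligibility,
              sum(x$significant), x$k_sigma))
  invisible(x)
}

#' @export
summary.difference_map <- function(object, ...) {
  sig <- count_significant(object)
  cat(sprintf("Difference map on %d x %d x %d grid\n",
              object$grid$shape[1], object$grid$shape[2], object$grid$shape[3]))
  cat(sprintf("  eligible voxels : %d (both > %d counts)\n",
              sum(object$eligible), object$min_count))
  cat(sprintf("  significant     : %d at %g sigma (%d deficits, %d excesses)\n",
              sig$n, object$k_sigma,
              sum(sig$voxels$delta < 0), sum(sig$voxels$delta > 0)))
  if (sig$n > 0) {
    cat("  strongest voxels:\n")
    print(utils::head(sig$voxels, 5), row.names = FALSE)
  }
  invisible(sig)
}

#' Count and list significant voxels
#'
#' @param map A [difference_map].
#' @return List with `n` (number of significant voxels) and `voxels`, a
#'   `data.frame` of their indices (0-based), center coordinates, counts and
#'   delta, sorted by |delta| descending.
#' @export
count_significant <- function(map) {
  stopifnot(inherits(map, "difference_map"))
  idx <- which(map$significant, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(list(n = 0L, voxels = data.frame(
      ix = integer(), iy = integer(), iz = integer(),
      x = numeric(), y = numeric(), z = numeric(),
      n1 = integer(), n2 = integer(), delta = integer())))
  }
  g <- map$grid
  vox <- data.frame(
    ix = idx[, 1] - 1L, iy = idx[, 2] - 1L, iz = idx[, 3] - 1L,
    x = g$origin[1] + (idx[, 1] - 0.5) * g$voxel_size[1],
    y = g$origin[2] + (idx[, 2] - 0.5) * g$voxel_size[2],
    z = g$origin[3] + (idx[, 3] - 0.5) * g$voxel_size[3],
    n1 = map$n1[idx], n2 = map$n2[idx], delta = map$delta[idx])
  vox <- vox[order(-abs(vox$delta), vox$ix, vox$iy, vox$iz), , drop = FALSE]
  rownames(vox) <- NULL
  list(n = nrow(vox), voxels = vox)
}

#' Expected number of voxels passing the threshold by chance
#'
#' Calibrates the Poisson significance threshold: for each eligible voxel
#' with mean mu, estimates by Monte Carlo the probability that two
#' independent Poisson counts X, Y ~ Pois(mu) satisfy
#' `|X - Y| >= k_sigma * sqrt(X + Y)`, and sums these probabilities over
#' voxels. Under the null (no anatomical change) this is the number of
#' significant voxels expected from counting statistics alone; an observed
#' count of the same order indicates a threshold working as designed.
#'
#' @param reference Either a `fragment_distribution` (its eligible voxel
#'   counts are used as plug-in Poisson means) or a numeric vector of
#'   per-voxel means.
#' @param min_count Eligibility threshold applied when `reference` is a
#'   distribution (voxels with counts > `min_count`).
#' @param k_sigma Threshold in Poisson sigma.
#' @param n_draws Monte Carlo replicates per voxel.
#' @param seed Optional integer seed.
#' @return List with `expected` (voxels), `se` (Monte Carlo standard error),
#'   `n_voxels` and `per_voxel_prob`.
#' @export
expected_chance_exceedances <- function(reference, min_count = 100,
                                        k_sigma = 2, n_draws = 1e4,
                                        seed = NULL) {
  if (inherits(reference, "fragment_distribution")) {
    mu <- as.numeric(reference$counts[reference$counts > min_count])
  } else {
    mu <- as.numeric(reference)
  }
  if (length(mu) == 0) stop("no eligible voxels")
  if (!is.null(seed)) set.seed(seed)
  nv <- length(mu)
  # one pooled draw block: n_draws replicate pairs for each voxel mean
  mu_rep <- rep(mu, each = n_draws)
  x <- stats::rpois(nv * n_draws, mu_rep)
  y <- stats::rpois(nv * n_draws, mu_rep)
  pass <- .poisson_significant(x, y, k_sigma)
  p <- as.numeric(rowsum(as.numeric(pass), rep(seq_len(nv), each = n_draws))) / n_draws
  expected <- sum(p)
  se <- sqrt(sum(p * (1 - p) / n_draws))
  list(expected = expected, se = se, n_voxels = nv, per_voxel_prob = p)
}

#' Depth profile of fragmentation vertices along the beam axis
#'
#' Integrates the vertex distribution over the transverse plane and histograms
#' it along z (the beam axis) in fixed-width bins (default 5 mm). Named
#' regions (e.g. phantom, target volume, nasopharynx) can be attached as
#' z-intervals for region-integrated comparisons.
#'
#' @param vertices `data.frame` with column `z` (mm).
#' @param bin_size Bin width along z, mm.
#' @param z_range Length-2 histogram range; defaults to the phantom extent
#'   (-80, 80) mm.
#' @param regions Named list of length-2 z-intervals.
#' @return Object of class `depth_profile` with `bin_edges`, `counts`,
#'   `regions` and `n_outside`.
#' @export
depth_profile <- function(vertices, bin_size = 5, z_range = c(-80, 80),
                          regions = list(phantom = c(-80, 80),
                                         ptv = c(-23, 23),
                                         nasopharynx = c(-15, -5))) {
  stopifnot(bin_size > 0, z_range[2] > z_range[1])
  edges <- seq(z_range[1], z_range[2], by = bin_size)
  if (edges[length(edges)] < z_range[2]) edges <- c(edges, z_range[2])
  i <- findInterval(vertices$z, edges, rightmost.closed = FALSE)
  inside <- i >= 1 & i <= length(edges) - 1 & vertices$z < edges[length(edges)]
  counts <- tabulate(i[inside], nbins = length(edges) - 1)
  structure(list(bin_edges = edges, counts = counts, regions = regions,
                 n_outside = sum(!inside)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %d bins of %g mm over [%g, %g] mm, %d vertices (+%d outside)\n",
              length(x$counts), diff(x$bin_edges[1:2]),
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              sum(x$counts), x$n_outside))
  invisible(x)
}

#' @export
plot.depth_profile <- function(x, ..., main = "Depth-fragment distribution") {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(mids, x$counts, type = "s", xlab = "z [mm]",
                 ylab = "fragment count", main = main, ...)
  for (r in x$regions) graphics::abline(v = r, lty = 3, col = "grey50")
  invisible(x)
}

#' Element-wise difference of two depth profiles
#'
#' @param p1,p2 `depth_profile`s with identical binning.
#' @return A list with `bin_edges` and `delta` (= p2 counts - p1 counts).
#' @export
profile_difference <- function(p1, p2) {
  stopifnot(inherits(p1, "depth_profile"), inherits(p2, "depth_profile"))
  if (!isTRUE(all.equal(p1$bin_edges, p2$bin_edges))) {
    stop("profiles must share identical binning")
  }
  list(bin_edges = p1$bin_edges, delta = p2$counts - p1$counts)
}

#' Region-integrated fragment count change
#'
#' Integrates the depth-profile difference (p2 - p1) over a z-interval.
#' Bins partially covered by the region contribute in proportion to their
#' overlap fraction.
#'
#' @param p1,p2 `depth_profile`s with identical binning.
#' @param region Length-2 z-interval, mm.
#' @return Integrated count change (numeric).
#' @export
region_delta <- function(p1, p2, region) {
  stopifnot(length(region) == 2, region[2] > region[1])
  d <- profile_difference(p1, p2)
  lo <- d$bin_edges[-length(d$bin_edges)]
  hi <- d$bin_edges[-1]
  frac <- pmax(0, pmin(hi, region[2]) - pmax(lo, region[1])) / (hi - lo)
  sum(d$delta * frac)
}

#' Relative shortfall of modelled against measured count reductions
#'
#' Given region-integrated fragment-count reductions observed in measurement
#' and predicted by a model (e.g. before- and after-insert reductions), returns
#' the fraction of the total measured reduction that the model fails to
#' reproduce, in percent: `100 * (sum|measured| - sum|modelled|) /
#' sum|measured|`.
#'
#' @param measured,modelled Numeric vectors of region-integrated count
#'   changes (signs are ignored; magnitudes are summed).
#' @return Shortfall in percent.
#' @export
deficit_shortfall <- function(measured, modelled) {
  sm <- sum(abs(measured))
  if (sm == 0) stop("measured reductions sum to zero")
  100 * (sm - sum(abs(modelled))) / sm
}

#' Diameter of a spherical target volume
#'
#' Convenience for plan geometry: the diameter (mm) of a sphere of the given
#' volume in milliliters, e.g. a 50 mL planning treatment volume corresponds
#' to a 46 mm diameter sphere (after rounding to the mm).
#'
#' @param volume_ml Volume in mL (= cm^3).
#' @return Diameter in mm.
#' @export
sphere_diameter_mm <- function(volume_ml) {
  (6 * volume_ml * 1000 / pi)^(1 / 3)
}

#' Image plot of one axial slice of a difference map
#'
#' @param x A [difference_map].
#' @param iy Row (y) index of the slice to show, 1-based; default middle.
#' @param ... Passed to [graphics::image].
#' @export
plot.difference_map <- function(x, iy = NULL, ...) {
  if (is.null(iy)) iy <- ceiling(x$grid$shape[2] / 2)
  sl <- x$delta[, iy, ]
  sl[!x$eligible[, iy, ]] <- NA
  zc <- grid_centers(x$grid, 3)
  xc <- grid_centers(x$grid, 1)
  lim <- max(abs(sl), 1, na.rm = TRUE)
  graphics::image(zc, xc, t(sl), col = grDevices::hcl.colors(31, "Blue-Red 2"),
                  zlim = c(-lim, lim), xlab = "z [mm] (beam axis)",
                  ylab = "x [mm]",
                  main = sprintf("count difference (y slice %d)", iy), ...)
  sig <- which(x$significant[, iy, ], arr.ind = TRUE)
  if (nrow(sig) > 0) {
    graphics::points(zc[sig[, 2]], xc[sig[, 1]], pch = 0, cex = 2)
  }
  invisible(x)
}
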