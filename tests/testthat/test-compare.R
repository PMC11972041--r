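test_that("voxelization uses half-open intervals and conserves counts", {
  grid <- grid_spec(origin = c(0, 0, 0), voxel_size = c(8, 8, 10),
                    shape = c(2, 2, 2))
  # single vertex at a voxel center
  d <- voxelize(data.frame(x = 4, y = 4, z = 5), grid)
  expect_equal(d$counts[1, 1, 1], 1L)
  expect_equal(sum(d$counts), 1)
  expect_equal(d$n_outside, 0)
  # a vertex exactly on an interior edge goes to the higher voxel
  d2 <- voxelize(data.frame(x = 8, y = 0, z = 0), grid)
  expect_equal(d2$counts[2, 1, 1], 1L)
  # conservation on uniform random vertices, some outside
  set.seed(10)
  n <- 1000
  verts <- data.frame(x = stats::runif(n, -4, 20), y = stats::runif(n, 0, 16),
                      z = stats::runif(n, 0, 25))
  d3 <- voxelize(verts, grid)
  expect_equal(d3$n_total_in_grid + d3$n_outside, n)
  expect_equal(sum(d3$counts), d3$n_total_in_grid)
})

make_dist <- function(counts, grid = NULL) {
  counts <- as.array(counts)
  if (is.null(grid)) grid <- grid_spec(c(0, 0, 0), c(8, 8, 10), dim(counts))
  structure(list(grid = grid, counts = counts,
                 n_total_in_grid = sum(counts), n_outside = 0L),
            class = "fragment_distribution")
}

test_that("the Poisson significance threshold is applied literally", {
  g <- grid_spec(c(0, 0, 0), c(8, 8, 10), c(3, 1, 1))
  n1 <- array(c(100, 500, 100), c(3, 1, 1))
  # 131 - 100 = 31 >= 2*sqrt(231) = 30.397 -> significant
  # 130 - 100 = 30 <  30.397               -> not significant
  # (eligibility threshold lowered so these counts are all eligible)
  n2 <- array(c(131, 500, 130), c(3, 1, 1))
  m <- difference_map(make_dist(n1, g), make_dist(n2, g), min_count = 50)
  expect_equal(as.vector(m$significant), c(TRUE, FALSE, FALSE))
  expect_equal(as.vector(m$delta), c(31, 0, 30))
  # identical counts are never significant
  m0 <- difference_map(make_dist(n1, g), make_dist(n1, g))
  expect_false(any(m0$significant))
  # below the eligibility count the threshold never fires
  n1b <- array(c(40, 500, 100), c(3, 1, 1))
  n2b <- array(c(400, 500, 130), c(3, 1, 1))
  mb <- difference_map(make_dist(n1b, g), make_dist(n2b, g), min_count = 100)
  expect_false(mb$significant[1, 1, 1])  # 40 vs 400 but ineligible
  expect_false(mb$eligible[1, 1, 1])
  # grid mismatch is an error
  g2 <- grid_spec(c(0, 0, 1), c(8, 8, 10), c(3, 1, 1))
  expect_error(difference_map(make_dist(n1, g), make_dist(n2, g2)),
               "identical grids")
})

test_that("significance mask is symmetric and deltas antisymmetric", {
  set.seed(2)
  g <- grid_spec(c(0, 0, 0), c(8, 8, 10), c(4, 4, 4))
  a <- make_dist(array(stats::rpois(64, 300), c(4, 4, 4)), g)
  b <- make_dist(array(stats::rpois(64, 300), c(4, 4, 4)), g)
  ab <- difference_map(a, b)
  ba <- difference_map(b, a)
  expect_equal(ab$significant, ba$significant)
  expect_equal(ab$eligible, ba$eligible)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(count_significant(ab)$n, count_significant(ba)$n)
})

test_that("threshold rule matches a literal reference on random counts", {
  set.seed(14)
  n1 <- stats::rpois(1e5, stats::runif(1e5, 0, 1000))
  n2 <- stats::rpois(1e5, stats::runif(1e5, 0, 1000))
  ours <- fragmon:::.poisson_significant(n1, n2, 2)
  ref <- abs(n2 - n1) >= 2 * sqrt(n1 + n2)  # the rule, written out
  expect_identical(ours, ref)
})

test_that("count_significant sorts voxels by |delta| and handles empties", {
  g <- grid_spec(c(0, 0, 0), c(8, 8, 10), c(3, 1, 1))
  n1 <- array(c(200, 200, 200), c(3, 1, 1))
  n2 <- array(c(200, 400, 290), c(3, 1, 1))
  m <- difference_map(make_dist(n1, g), make_dist(n2, g))
  cs <- count_significant(m)
  expect_equal(cs$n, 2)
  expect_equal(cs$voxels$delta, c(200, 90))  # descending |delta|
  m0 <- difference_map(make_dist(n1, g), make_dist(n1, g))
  expect_equal(count_significant(m0)$n, 0)
})

test_that("chance-exceedance calibration approaches the normal limit", {
  # large mean: per-voxel probability ~ 2 * (1 - Phi(2)) ~ 0.0455
  one <- expected_chance_exceedances(10000, n_draws = 2e4, seed = 1)
  expect_equal(one$expected, 2 * (1 - stats::pnorm(2)),
               tolerance = 4 * one$se / one$expected)
  # a very hard threshold is never exceeded
  none <- expected_chance_exceedances(rep(400, 50), k_sigma = 50,
                                      n_draws = 2000, seed = 2)
  expect_equal(none$expected, 0)
  expect_error(expected_chance_exceedances(numeric()), "no eligible voxels")
})

test_that("null significant-voxel fraction converges to the 2 sigma rate", {
  # two Poisson draws per voxel at equal large means: the fraction of
  # significant voxels approaches 4.55%
  set.seed(33)
  n <- 1e4
  mu <- 2000
  x <- stats::rpois(n, mu); y <- stats::rpois(n, mu)
  frac <- mean(fragmon:::.poisson_significant(x, y, 2))
  p <- 2 * (1 - stats::pnorm(2))
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n) + 0.003)
})

test_that("depth profiles bin along the beam axis with region bookkeeping", {
  p <- depth_profile(data.frame(z = rep(12, 10)), bin_size = 5,
                     z_range = c(0, 40))
  expect_equal(p$counts[3], 10)  # bin [10, 15)
  expect_equal(sum(p$counts), 10)
  # identical inputs give a zero difference everywhere
  d <- profile_difference(p, p)
  expect_true(all(d$delta == 0))
  # region integration with partial bins: region [11, 14] overlaps
  # only bin [10,15) by 3/5
  p1 <- depth_profile(data.frame(z = c(rep(12, 50), rep(22, 20))),
                      bin_size = 5, z_range = c(0, 40))
  p2 <- p1; p2$counts[3] <- p2$counts[3] - 50
  expect_equal(region_delta(p1, p2, c(10, 15)), -50)
  expect_equal(region_delta(p1, p2, c(11, 14)), -50 * 3 / 5)
  expect_equal(region_delta(p1, p1, c(0, 40)), 0)
  expect_error(profile_difference(p, depth_profile(data.frame(z = 1),
                                                   bin_size = 2,
                                                   z_range = c(0, 40))),
               "identical binning")
})

test_that("model shortfall arithmetic reproduces the worked example", {
  # measured reductions -33000 (before) and -16000 (after) against modelled
  # -28000 and -13000: shortfall (49000 - 41000) / 49000 ~ 16%
  s <- deficit_shortfall(c(-33000, -16000), c(-28000, -13000))
  expect_equal(s, 100 * 8000 / 49000)
  expect_equal(round(s), 16)
})

test_that("sphere diameter for a 50 mL target volume rounds to 46 mm", {
  expect_equal(round(sphere_diameter_mm(50)), 46)
  expect_equal(sphere_diameter_mm(50), (6 * 50000 / pi)^(1 / 3))
})
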