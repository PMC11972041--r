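test_that("plan generation spans the energy range deterministically", {
  p1 <- generate_plan(n_layers = 1, spots_per_layer = 1)
  expect_equal(nrow(p1$beam_log), 1)
  p25 <- generate_plan(n_layers = 25, spots_per_layer = 10)
  e <- unique(p25$beam_log$energy_mev_u)
  expect_equal(e, seq(153, 250, length.out = 25))
  expect_equal(range(e), c(153, 250))
  # identical calls give identical plans
  expect_identical(generate_plan(seed = 4), generate_plan(seed = 4))
  # delivery intervals are disjoint and ordered
  bl <- p25$beam_log
  expect_true(all(bl$t_start_ns[-1] > bl$t_end_ns[-nrow(bl)]))
})

test_that("vertex depths follow the production density", {
  model_flat <- emission_model(primary_att_length = 1e9)
  ph <- phantom_model(cavity_density = 1)  # homogeneous
  # uniform density, no attenuation, range beyond the phantom:
  # depths are uniform over the full phantom
  set.seed(1)
  z <- sample_vertex_depth(1e4, 250, ph, model_flat)
  ks <- suppressWarnings(stats::ks.test(z, "punif", ph$entry_z, ph$exit_z))
  expect_gt(ks$p.value, 0.01)
  # range truncation: a low energy stops inside the phantom
  R <- primary_range(153, model_flat)
  z2 <- sample_vertex_depth(1e4, 153, ph, model_flat)
  expect_lt(max(z2), ph$entry_z + R + 1)
  expect_gt(max(z2), ph$entry_z + R - 2)
})

test_that("the insert raises in-cavity production and lowers it beyond", {
  # cavity at density 0.49, insert at 0.98: the local density doubles, so
  # in-cavity production (before survival losses) doubles
  ph0 <- phantom_model(cavity_density = 0.49)
  ph1 <- with_insert(ph0, density = 0.98)
  model_flat <- emission_model(primary_att_length = 1e9)
  set.seed(2)
  n <- 1e5
  z0 <- sample_vertex_depth(n, 250, ph0, model_flat, crossing = TRUE)
  z1 <- sample_vertex_depth(n, 250, ph1, model_flat, crossing = TRUE)
  g0 <- attr(z0, "grid"); g1 <- attr(z1, "grid")
  inb <- g0$z >= -15 & g0$z < -5
  # production-rate ratio inside the cavity (unnormalized density f)
  expect_equal(sum(g1$f[inb]) / sum(g0$f[inb]), 2, tolerance = 1e-6)
  # with attenuation on, production beyond the insert is strictly lower
  model <- emission_model()
  gg0 <- attr(sample_vertex_depth(10, 250, ph0, model, crossing = TRUE), "grid")
  gg1 <- attr(sample_vertex_depth(10, 250, ph1, model, crossing = TRUE), "grid")
  beyond <- gg0$z > -5
  expect_true(all(gg1$f[beyond] < gg0$f[beyond]))
  # and the end of range moves upstream for a stopping energy
  gs0 <- attr(sample_vertex_depth(10, 153, ph0, model, crossing = TRUE), "grid")
  gs1 <- attr(sample_vertex_depth(10, 153, ph1, model, crossing = TRUE), "grid")
  expect_lt(max(gs1$z[gs1$f > 0]), max(gs0$z[gs0$f > 0]))
})

test_that("emission directions are forward peaked with scale theta0", {
  set.seed(3)
  # tight peaking: everything within a milliradian-scale cone
  d0 <- sample_emission_direction(1000, emission_model(theta0 = 1e-4))
  expect_true(all(acos(d0[, 3]) < 1e-3))
  # mean polar angle ~ theta0 for theta0 << pi/2
  n <- 1e5
  d <- sample_emission_direction(n, emission_model(theta0 = 0.2))
  th <- acos(pmin(d[, 3], 1))
  expect_lt(abs(mean(th) - 0.2), 3 * stats::sd(th) / sqrt(n) + 0.002)
  # a wider theta0 pushes more emission into the 25-35 degree annulus
  th_narrow <- acos(sample_emission_direction(n, emission_model(theta0 = 0.1))[, 3])
  th_wide <- acos(sample_emission_direction(n, emission_model(theta0 = 0.5))[, 3])
  band <- function(x) mean(x > 25 * pi / 180 & x < 35 * pi / 180)
  expect_gt(band(th_wide), band(th_narrow))
  # unit norms
  expect_equal(rowSums(d[1:100, ]^2), rep(1, 100), tolerance = 1e-12)
})

test_that("fragment transport applies the closed-form attenuation", {
  ph_air <- phantom_model(cavity_density = 1e-9)
  ph_ins <- with_insert(ph_air, density = 0.98)
  model <- emission_model(mcs_sigma = 0)
  # path along +z through the 10 mm cavity: the filled cavity multiplies
  # survival by exp(-0.98 * 10 / 400)
  o <- c(0, 0, -40); d <- c(0, 0, 1)
  p0 <- fragment_survival_prob(o, d, ph_air, model)
  p1 <- fragment_survival_prob(o, d, ph_ins, model)
  expect_equal(p1 / p0, exp(-9.8 / 400), tolerance = 1e-9)
  # no attenuation, no scattering: the ray is unchanged and always survives
  model_free <- emission_model(fragment_att_length = 1e12, mcs_sigma = 0)
  tr <- transport_fragment(o, d, ph_ins, model_free)
  expect_true(tr$survived)
  expect_equal(tr$direction[1, ], d, ignore_attr = TRUE)
  # oblique path: integral scales with 1/cos(angle) in uniform material
  ph_uni <- phantom_model(cavity_density = 1)
  d30 <- c(0, sin(pi / 6), cos(pi / 6))
  w_straight <- -log(fragment_survival_prob(c(0, 0, 0), c(0, 0, 1), ph_uni, model))
  w_oblique <- -log(fragment_survival_prob(c(0, 0, 0), d30, ph_uni, model))
  expect_equal(w_oblique / w_straight, 1 / cos(pi / 6), tolerance = 1e-6)
})

test_that("scattering blur preserves norms and has the set width", {
  set.seed(6)
  n <- 2e4
  d <- matrix(rep(c(0, 0.5, sqrt(0.75)), each = n), ncol = 3)
  model <- emission_model(mcs_sigma = 0.008)
  ph <- phantom_model()
  tr <- transport_fragment(matrix(0, n, 3), d, ph, model)
  expect_equal(rowSums(tr$direction^2), rep(1, n), tolerance = 1e-9)
  ang <- acos(pmin(rowSums(tr$direction * d), 1))
  # 2D Gaussian deflection: mean angle = sigma * sqrt(pi/2)
  expect_equal(mean(ang), 0.008 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("detector response thresholds, spreads and quantizes hits", {
  geom <- tracker_geometry()
  model <- emission_model()
  # a ray through both layer centers is detected with centroids at center
  o <- c(0, 0, 0)
  d <- geom$focus_direction
  set.seed(9)
  resp <- detector_response(o, d, 1000, geom, model)
  expect_true(resp$detected)
  expect_setequal(unique(resp$hits$layer), c("front", "back"))
  np <- geom$pixels_per_layer
  for (lid in c("front", "back")) {
    h <- resp$hits[resp$hits$layer == lid, ]
    centroid <- c(sum(h$col * h$energy_kev), sum(h$row * h$energy_kev)) /
      sum(h$energy_kev)
    expect_lt(abs(centroid[1] - (np[1] - 1) / 2), 0.75)
    expect_lt(abs(centroid[2] - (np[2] - 1) / 2), 0.75)
  }
  # times are quantized to the 1.5625 ns clock
  expect_true(all(resp$hits$toa_ns %% TOA_QUANTUM_NS == 0))
  # a deposit below the 3 keV pixel threshold leaves no hits
  tiny <- emission_model(edep_median = 2, edep_sdlog = 1e-6)
  resp2 <- detector_response(o, d, 1000, geom, tiny)
  expect_equal(nrow(resp2$hits), 0)
  expect_false(resp2$detected)
  # a ray through the front layer near its edge diverges off the smaller
  # angular footprint of the back layer: front hits only -> not detected
  p_edge <- geom$layers$front$center + 13.5 * geom$layers$front$e1
  d_miss <- p_edge / sqrt(sum(p_edge^2))
  resp3 <- detector_response(c(0, 0, 0), d_miss, 0, geom, model)
  expect_true(resp3$hit_front[1])
  expect_false(resp3$hit_back[1])
  expect_false(resp3$detected)
  expect_true(all(resp3$hits$layer == "front"))
})

test_that("full acquisitions are reproducible and scale linearly", {
  plan <- tiny_plan(1500)
  s1 <- simulate_fraction(plan, n_repetitions = 2, seed = 7)
  s2 <- simulate_fraction(plan, n_repetitions = 2, seed = 7)
  expect_identical(s1$repetitions, s2$repetitions)
  s3 <- simulate_fraction(plan, n_repetitions = 2, seed = 8)
  expect_false(identical(s1$repetitions, s3$repetitions))
  # doubling the primaries doubles the expected detected count
  s2x <- simulate_fraction(plan, n_repetitions = 2, seed = 9,
                           n_primaries = 3000)
  n1 <- s1$stats[["n_detected"]]; n2 <- s2x$stats[["n_detected"]]
  expect_lt(abs(n2 - 2 * n1), 3 * sqrt(n2 + 4 * n1) + 1)
  # detected fraction of produced fragments is tiny (small solid angle,
  # forward peaking at 30 degrees)
  expect_lt(n1 / s1$stats[["n_produced"]], 0.01)
  # in-band bookkeeping is consistent
  expect_gte(s1$stats[["n_inband"]], n1)
  expect_gte(s1$stats[["n_produced"]], s1$stats[["n_inband"]])
})

test_that("detected fraction increases with the forward-peaking scale", {
  plan <- tiny_plan(1500)
  f <- vapply(c(0.15, 0.35, 0.6), function(t0) {
    s <- simulate_fraction(plan, model = emission_model(theta0 = t0),
                           n_repetitions = 2, seed = 13)
    s$stats[["n_detected"]] / s$stats[["n_produced"]]
  }, 0)
  # the tracker sits at 30 degrees: widening the emission cone from a very
  # forward-peaked one raises the acceptance
  expect_true(all(diff(f) > 0))
})

test_that("every detected truth vertex yields a reconstructable track", {
  sim <- simulate_fraction(tiny_plan(2000), n_repetitions = 1, seed = 17)
  rep1 <- sim$repetitions[[1]]
  expect_true(all(rep1$truth$detected))
  reco <- run_reconstruction(rep1$hits_front, rep1$hits_back, sim$beam_log)
  # vertex count matches detected truth minus beam-gap/degenerate/accidental
  # losses (a small margin)
  expect_gt(nrow(reco$vertices), 0.97 * nrow(rep1$truth))
  linked <- link_truth(reco$vertices, rep1$truth)
  expect_gt(mean(!is.na(linked$frag_id)), 0.97)
})
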