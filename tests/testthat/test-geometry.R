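test_that("closest approach reproduces hand-solved configurations", {
  # coplanar intersecting lines meet at a single point
  a <- line3(c(0, 0, 0), c(0, 0, 1))
  b <- line3(c(10, 0, 50), c(0.5, 0, 0.86603))
  ca <- closest_approach(a, b)
  expect_false(ca$degenerate)
  expect_lt(ca$distance, 1e-4)
  expect_equal(ca$midpoint, c(0, 0, 32.6795), tolerance = 1e-4,
               ignore_attr = TRUE)

  # skew perpendicular lines: unit separation, midpoint halfway
  b2 <- line3(c(1, 0, 0), c(0, 1, 0))
  ca2 <- closest_approach(a, b2)
  expect_equal(ca2$distance, 1)
  expect_equal(ca2$point_on_a, c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(ca2$point_on_b, c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(ca2$midpoint, c(0.5, 0, 0), ignore_attr = TRUE)

  # identical lines: shared origin, zero distance
  ca3 <- closest_approach(a, a)
  expect_true(ca3$degenerate)
  expect_equal(ca3$distance, 0)
  expect_equal(ca3$midpoint, a$origin)

  # parallel distinct lines: degenerate with the perpendicular distance
  b4 <- line3(c(1, 0, 0), c(0, 0, 1))
  ca4 <- closest_approach(a, b4)
  expect_true(ca4$degenerate)
  expect_equal(ca4$distance, 1)
  expect_true(all(is.na(ca4$midpoint)))
})

test_that("closest approach matches brute-force minimization on random pairs", {
  set.seed(42)
  for (i in 1:200) {
    a <- random_line(); b <- random_line()
    ca <- closest_approach(a, b)
    if (ca$degenerate) next
    bf <- brute_closest(a, b)
    expect_lt(abs(ca$distance - bf$distance), 1e-4)           # mm, absolute
    expect_lt(max(abs(ca$midpoint - bf$midpoint)), 1e-3)
    # connecting segment orthogonal to both directions
    seg <- ca$point_on_a - ca$point_on_b
    if (ca$distance > 1e-8) {
      expect_lt(abs(sum(seg * a$direction)), 1e-6 * ca$distance + 1e-9)
      expect_lt(abs(sum(seg * b$direction)), 1e-6 * ca$distance + 1e-9)
    }
    # symmetric under argument swap
    ca_sw <- closest_approach(b, a)
    expect_equal(ca_sw$midpoint, ca$midpoint, tolerance = 1e-9)
  }
})

test_that("coplanar non-parallel lines intersect exactly", {
  set.seed(7)
  for (i in 1:50) {
    a <- random_line()
    # construct a line through a point of a, with an independent direction
    p <- a$origin + stats::runif(1, -20, 20) * a$direction
    b <- line3(p, stats::rnorm(3))
    ca <- closest_approach(a, b)
    if (ca$degenerate) next
    expect_lt(ca$distance, 1e-9)
    expect_equal(ca$midpoint, p, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("vectorized closest approach agrees with the scalar primitive", {
  set.seed(11)
  n <- 100
  o1 <- matrix(stats::runif(3 * n, -50, 50), n)
  o2 <- matrix(stats::runif(3 * n, -50, 50), n)
  u1 <- matrix(stats::rnorm(3 * n), n); u1 <- u1 / sqrt(rowSums(u1^2))
  u2 <- matrix(stats::rnorm(3 * n), n); u2 <- u2 / sqrt(rowSums(u2^2))
  many <- fragmon:::.closest_approach_many(o1, u1, o2, u2)
  for (i in seq_len(n)) {
    ca <- closest_approach(line3(o1[i, ], u1[i, ]), line3(o2[i, ], u2[i, ]))
    expect_equal(many$distance[i], ca$distance, tolerance = 1e-9)
    expect_equal(many$midpoint[i, ], ca$midpoint, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("tracker geometry places the layers on the focus line", {
  geom <- tracker_geometry()
  # front layer center sits 167 mm from the isocenter on the focus line
  expect_equal(sqrt(sum(geom$layers$front$center^2)), 167)
  expect_equal(sqrt(sum(geom$layers$back$center^2)), 167 + 20.3)
  # focus line at 30 degrees to the beam axis
  expect_equal(acos(geom$focus_direction[3]) * 180 / pi, 30)
  # layer centers separated by the layer separation along the focus line
  d <- geom$layers$back$center - geom$layers$front$center
  expect_equal(sqrt(sum(d^2)), geom$layer_separation)
  expect_equal(sum(d * geom$focus_direction), geom$layer_separation)
  # derived pixel counts from area over pitch
  expect_equal(geom$pixels_per_layer, c(509L, 254L))
})

test_that("sensor-to-room mapping has the right scale, center and inverse", {
  geom0 <- tracker_geometry(tilt_deg = 0)
  np <- geom0$pixels_per_layer
  # grid-center pixel coordinate maps to the front layer center, 167 mm out
  p <- sensor_to_room((np[1] - 1) / 2, (np[2] - 1) / 2, "front", geom0)
  expect_equal(sqrt(sum(p^2)), 167, tolerance = 1e-9)
  # neighboring columns are one pixel pitch apart in space
  p2 <- sensor_to_room(c(100, 101), c(50, 50), "front", geom0)
  expect_equal(sqrt(sum((p2[2, ] - p2[1, ])^2)), 0.055, tolerance = 1e-12)
  # round trip on random in-plane points
  set.seed(3)
  col <- stats::runif(500, 0, np[1] - 1)
  row <- stats::runif(500, 0, np[2] - 1)
  geom <- tracker_geometry()  # with tilt
  for (lid in c("front", "back")) {
    pts <- sensor_to_room(col, row, lid, geom)
    back <- room_to_sensor(pts, lid, geom)
    expect_equal(back$col, col, tolerance = 1e-9)
    expect_equal(back$row, row, tolerance = 1e-9)
  }
  expect_error(sensor_to_room(np[1] + 3, 0, "front", geom), "out of range")
})

test_that("the in-support tilt is a rotation about the focus line", {
  g0 <- tracker_geometry(tilt_deg = 0)
  g1 <- tracker_geometry(tilt_deg = 1.6)
  corner0 <- sensor_to_room(0, 0, "front", g0)[1, ]
  corner1 <- sensor_to_room(0, 0, "front", g1)[1, ]
  expect_gt(sqrt(sum((corner1 - corner0)^2)), 0.1)
  # rotating the tilted corner back reproduces the untilted one
  u <- g0$focus_direction
  back <- fragmon:::.rotate_about(corner1, u, -1.6 * pi / 180)
  expect_equal(back, corner0, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("acceptance solid angle matches the small-angle estimate", {
  geom <- tracker_geometry(tilt_deg = 0)
  sa <- acceptance_solid_angle(geom, n_samples = 2e5, seed = 1,
                               layers = "front")
  analytic <- prod(geom$active_area) / geom$front_layer_distance^2
  expect_equal(sa$omega, analytic, tolerance = 0.02)
  # doubling the distance quarters the single-layer acceptance
  geom2 <- tracker_geometry(tilt_deg = 0, front_layer_distance = 334)
  sa2 <- acceptance_solid_angle(geom2, n_samples = 2e5, seed = 2,
                                layers = "front")
  expect_equal(sa2$omega, analytic / 4, tolerance = 0.02)
  # coincidence acceptance is a subset of the single-layer acceptance
  both <- acceptance_solid_angle(geom, n_samples = 1e5, seed = 3)
  expect_lt(both$omega, sa$omega)
  expect_gt(both$omega, 0)
  expect_error(acceptance_solid_angle(geom, origin = geom$layers$front$center,
                                      n_samples = 1e4), "layer plane")
})
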