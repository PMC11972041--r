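## Phenomenological scanned-beam + fragment-emission generator
##
## The generator is NOT a transport Monte Carlo: it produces data with the
## statistical structure the analysis downstream assumes — depth-dependent
## vertex production along each pencil beam, exponentially forward-peaked
## emission, exponential attenuation of primaries and fragments, water-
## equivalent range truncation, a net Gaussian multiple-Coulomb-scattering
## blur, and a two-layer pixel detector response with charge sharing and a
## per-pixel energy threshold. A single effective fragment species is used.
##
## Emission-cone restriction (variance reduction, statistically exact): a
## fragment's direction is independent of its vertex, and only directions
## inside a conservative (theta, phi) band around the tracker can ever be
## detected. Fragment counts are therefore Poisson-thinned into an "in band"
## population that is simulated in full and an out-of-band population that is
## only counted. The band depends on the spot and the vertex depth bin; the
## same band enters both the thinning probability and the conditional
## sampling, so the detected-fragment distribution is identical to a full
## simulation (up to the conservativeness of the band, whose margins cover
## the lateral beam spread at 5 sigma and the scattering blur at >5 sigma).

#' Head-phantom model
#'
#' A slab phantom along the beam axis with an internal cavity box
#' (the nasopharynx) that can be filled by a soft-tissue-equivalent insert.
#' Densities are relative to water. The default cavity is 25 x 25 x 10 mm
#' (about 6 mL) centered on the beam axis just upstream of the isocenter,
#' air-filled unless the insert is present; the insert density 0.98
#' corresponds to a mean CT number of about -20 HU.
#'
#' @param entry_z,exit_z Phantom extent along the beam axis, mm.
#' @param base_density Bulk soft-tissue density (relative to water).
#' @param density_layers Optional `data.frame(z_lo, z_hi, density)` of
#'   z-slabs (e.g. bone) overriding the base density; must not overlap the
#'   cavity.
#' @param cavity_z Length-2 z-interval of the cavity, mm.
#' @param cavity_lateral Length-2 lateral (x, y) extent of the cavity, mm.
#' @param cavity_center Length-2 lateral center of the cavity, mm.
#' @param cavity_density Density of the empty cavity (air-like default).
#' @param insert Logical: is the insert present?
#' @param insert_density Density of the insert material.
#' @param lateral_half_extent Lateral half-extent of the phantom (x, y), mm.
#' @return Object of class `phantom_model`.
#' @export
phantom_model <- function(entry_z = -80, exit_z = 80, base_density = 1,
                          density_layers = NULL,
                          cavity_z = c(-15, -5), cavity_lateral = c(25, 25),
                          cavity_center = c(0, 0), cavity_density = 0.05,
                          insert = FALSE, insert_density = 0.98,
                          lateral_half_extent = c(80, 80)) {
  stopifnot(exit_z > entry_z, base_density > 0, cavity_density > 0,
            insert_density > 0, cavity_z[1] >= entry_z, cavity_z[2] <= exit_z,
            cavity_z[2] > cavity_z[1])
  structure(list(entry_z = entry_z, exit_z = exit_z,
                 base_density = base_density,
                 density_layers = density_layers,
                 cavity_z = cavity_z,
                 cavity_lateral = cavity_lateral,
                 cavity_center = cavity_center,
                 cavity_density = cavity_density,
                 insert = insert, insert_density = insert_density,
                 lateral_half_extent = lateral_half_extent),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("<phantom_model> z in [%g, %g] mm, base density %.2f\n",
              x$entry_z, x$exit_z, x$base_density))
  cat(sprintf("  cavity z [%g, %g] x lateral %g x %g mm: %s (density %.2f)\n",
              x$cavity_z[1], x$cavity_z[2], x$cavity_lateral[1],
              x$cavity_lateral[2],
              if (x$insert) "insert present" else "empty",
              .box_density(x)))
  invisible(x)
}

#' Fill (or empty) the phantom cavity
#'
#' @param phantom A [phantom_model].
#' @param density Insert density; defaults to the phantom's `insert_density`.
#' @return The phantom with the insert present (`with_insert`) or absent
#'   (`without_insert`).
#' @export
with_insert <- function(phantom, density = NULL) {
  stopifnot(inherits(phantom, "phantom_model"))
  phantom$insert <- TRUE
  if (!is.null(density)) phantom$insert_density <- density
  phantom
}

#' @rdname with_insert
#' @export
without_insert <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_model"))
  phantom$insert <- FALSE
  phantom
}

.box_density <- function(phantom) {
  if (phantom$insert) phantom$insert_density else phantom$cavity_density
}

## base (cavity-free) density at depth z: bulk + optional slabs
.rho_base_z <- function(phantom, z) {
  rho <- rep(phantom$base_density, length(z))
  dl <- phantom$density_layers
  if (!is.null(dl)) {
    for (i in seq_len(nrow(dl))) {
      rho[z >= dl$z_lo[i] & z < dl$z_hi[i]] <- dl$density[i]
    }
  }
  rho[z < phantom$entry_z | z > phantom$exit_z] <- 0
  rho
}

## cumulative water-equivalent depth of the base profile from entry_z to z
.wed_base <- function(phantom, z) {
  zc <- pmin(pmax(z, phantom$entry_z), phantom$exit_z)
  w <- phantom$base_density * (zc - phantom$entry_z)
  dl <- phantom$density_layers
  if (!is.null(dl)) {
    for (i in seq_len(nrow(dl))) {
      ov <- pmax(0, pmin(zc, dl$z_hi[i]) - dl$z_lo[i])
      w <- w + (dl$density[i] - phantom$base_density) * ov
    }
  }
  w
}

#' Density of the phantom at room-frame points
#'
#' @param phantom A [phantom_model].
#' @param x,y,z Coordinates, mm (vectors of equal length).
#' @return Densities relative to water (0 outside the phantom).
#' @export
phantom_density <- function(phantom, x, y, z) {
  rho <- .rho_base_z(phantom, z)
  inside_lat <- abs(x) <= phantom$lateral_half_extent[1] &
                abs(y) <= phantom$lateral_half_extent[2]
  rho[!inside_lat] <- 0
  in_box <- z >= phantom$cavity_z[1] & z < phantom$cavity_z[2] &
    abs(x - phantom$cavity_center[1]) <= phantom$cavity_lateral[1] / 2 &
    abs(y - phantom$cavity_center[2]) <= phantom$cavity_lateral[2] / 2
  rho[in_box & inside_lat] <- .box_density(phantom)
  rho
}

#' Fragment emission and transport model
#'
#' Parameters of the phenomenological emission model. Angles in radians,
#' lengths in mm, energies in keV.
#'
#' @param theta0 Forward-peaking scale of the emission polar angle: the
#'   angular density falls as `exp(-theta / theta0)` on `[0, pi/2]`.
#' @param production_rate Fragment production rate per primary, per mm of
#'   path, per unit density. Its default is calibrated so that a
#'   full-statistics reference acquisition (7 summed repetitions at
#'   signature scale, see [signature_primaries]) yields about 2e6 detected
#'   fragments, the counting regime of a clinical-plan acquisition with a
#'   seven-tracker system.
#' @param primary_att_length Attenuation length of primaries in unit-density
#'   tissue, mm (survival `exp(-WED / primary_att_length)`).
#' @param fragment_att_length Attenuation length of fragments, mm of
#'   water-equivalent path.
#' @param spot_sigma Nominal lateral pencil-beam spread at the isocenter, mm.
#'   The generator samples each primary's lateral position from the per-spot
#'   `sigma_mm` recorded in the delivery log (this value is
#'   [generate_plan]'s default for that column).
#' @param mcs_sigma Net multiple-Coulomb-scattering angular blur applied to
#'   each fragment direction, rad.
#' @param edep_median,edep_sdlog Lognormal per-layer energy-deposit sampler
#'   (median keV, log-sd).
#' @param range_alpha,range_p Power-law range-energy mapping
#'   `R = range_alpha * E^range_p` (mm of water-equivalent depth, E in
#'   MeV/u). The default `range_alpha` is scaled so that `R(250) = 270` mm.
#' @param threshold_kev Per-pixel detection threshold.
#' @return Object of class `emission_model`.
#' @export
emission_model <- function(theta0 = 0.35,
                           production_rate = 0.068,
                           primary_att_length = 250,
                           fragment_att_length = 400,
                           spot_sigma = 2.0,
                           mcs_sigma = 0.008,
                           edep_median = 40,
                           edep_sdlog = 0.5,
                           range_alpha = 270 / 250^1.77,
                           range_p = 1.77,
                           threshold_kev = 3) {
  stopifnot(theta0 > 0, production_rate > 0, primary_att_length > 0,
            fragment_att_length > 0, spot_sigma >= 0, mcs_sigma >= 0,
            range_alpha > 0, range_p > 0)
  structure(as.list(environment()), class = "emission_model")
}

#' Water-equivalent range of a primary
#' @param energy Beam energy, MeV/u.
#' @param model An [emission_model].
#' @return Range in mm of water-equivalent depth.
#' @export
primary_range <- function(energy, model) model$range_alpha * energy^model$range_p

#' Generate a raster-scanned delivery plan and its beam log
#'
#' Spots are laid out on a centered rectangular raster per energy layer;
#' layer energies are linearly spaced across `energy_range`. Spots are
#' delivered sequentially with a constant primary rate, so the beam log's
#' delivery intervals are disjoint and time-ordered.
#'
#' @param n_layers Number of energy layers.
#' @param spots_per_layer Spots in each layer.
#' @param n_primaries Primaries per spot.
#' @param energy_range Length-2 energy span, MeV/u.
#' @param spot_spacing Raster spacing, mm.
#' @param spot_sigma Nominal lateral beam spread recorded in the log, mm.
#' @param delivery_rate Primaries per second (sets spot durations).
#' @param seed Unused randomness hook (the raster plan is deterministic);
#'   kept so that plan generation has a stable signature alongside the
#'   stochastic generator stages.
#' @return List with `beam_log` (see [read_beam_log]) and `layers`
#'   (`data.frame` of layer energies).
#' @export
generate_plan <- function(n_layers = 5, spots_per_layer = 40,
                          n_primaries = 2000, energy_range = c(153, 250),
                          spot_spacing = 3, spot_sigma = 2,
                          delivery_rate = 2e6, seed = NULL) {
  stopifnot(n_layers >= 1, spots_per_layer >= 1, n_primaries >= 1)
  if (!is.null(seed)) set.seed(seed)
  energies <- if (n_layers == 1) mean(energy_range) else {
    seq(energy_range[1], energy_range[2], length.out = n_layers)
  }
  nx <- ceiling(sqrt(spots_per_layer * 1.6))
  ny <- ceiling(spots_per_layer / nx)
  gx <- (seq_len(nx) - (nx + 1) / 2) * spot_spacing
  gy <- (seq_len(ny) - (ny + 1) / 2) * spot_spacing
  g <- expand.grid(x = gx, y = gy)[seq_len(spots_per_layer), ]
  dur <- n_primaries / delivery_rate * 1e9  # ns
  gap <- 0.1 * dur + 1000
  n_spots <- n_layers * spots_per_layer
  t_start <- (seq_len(n_spots) - 1) * (dur + gap)
  beam_log <- data.frame(
    spot_id = seq_len(n_spots),
    energy_mev_u = rep(energies, each = spots_per_layer),
    x_mm = rep(g$x, n_layers),
    y_mm = rep(g$y, n_layers),
    sigma_mm = spot_sigma,
    n_primaries = n_primaries,
    t_start_ns = t_start,
    t_end_ns = t_start + dur
  )
  list(beam_log = beam_log,
       layers = data.frame(layer = seq_len(n_layers), energy_mev_u = energies))
}

## --- depth-dependent vertex production ------------------------------------

## 1D production grid for one beam energy and one lateral class
## (crossing = the primary's straight path traverses the cavity box).
## f(z) dz = expected fragments per primary produced in [z, z+dz):
##   f = production_rate * rho(z) * exp(-WED(z) / primary_att_length)
## truncated where WED exceeds the water-equivalent range.
.depth_grid <- function(phantom, model, energy, crossing, dz = 0.5) {
  z <- seq(phantom$entry_z + dz / 2, phantom$exit_z - dz / 2, by = dz)
  rho <- .rho_base_z(phantom, z)
  wed <- .wed_base(phantom, z)
  if (crossing) {
    b0 <- phantom$cavity_z[1]; b1 <- phantom$cavity_z[2]
    rb <- .box_density(phantom)
    inb <- z >= b0 & z < b1
    rho[inb] <- rb
    ov <- pmax(0, pmin(z, b1) - b0)
    wed <- wed + rb * ov - (.wed_base(phantom, pmin(z, b1)) - .wed_base(phantom, b0))
  }
  R <- primary_range(energy, model)
  alive <- wed < R
  f <- model$production_rate * rho * exp(-wed / model$primary_att_length) * alive
  list(z = z, dz = dz, f = f, yield = sum(f) * dz)
}

#' Sample fragmentation-vertex depths along a pencil beam
#'
#' Vertex depths follow the production density: local density times the
#' surviving primary fraction, truncated at the primary's water-equivalent
#' range. With the insert present the cavity densifies, producing more
#' vertices inside the cavity, attenuating the primaries crossing it, and
#' pulling the end of range upstream.
#'
#' @param n Number of depths to sample.
#' @param energy Beam energy, MeV/u.
#' @param phantom A [phantom_model].
#' @param model An [emission_model].
#' @param crossing Does the primary's lateral position traverse the cavity
#'   box?
#' @return Numeric vector of z positions, mm. The production grid is
#'   attached as attribute `"grid"`.
#' @export
sample_vertex_depth <- function(n, energy, phantom, model, crossing = FALSE) {
  g <- .depth_grid(phantom, model, energy, crossing)
  if (sum(g$f) <= 0) stop("no production along this beam (zero density or range)")
  i <- sample.int(length(g$z), n, replace = TRUE, prob = g$f)
  z <- g$z[i] + stats::runif(n, -g$dz / 2, g$dz / 2)
  attr(z, "grid") <- g
  z
}

## --- emission direction ----------------------------------------------------

.theta_norm <- function(theta0) 1 - exp(-pi / (2 * theta0))

## P(theta in [a, b]) under density ~ exp(-theta/theta0) on [0, pi/2]
.p_theta_band <- function(theta0, a, b) {
  a <- pmin(pmax(a, 0), pi / 2)
  b <- pmin(pmax(b, 0), pi / 2)
  pmax(exp(-a / theta0) - exp(-b / theta0), 0) / .theta_norm(theta0)
}

.sample_theta_band <- function(n, theta0, a, b) {
  ea <- exp(-a / theta0); eb <- exp(-b / theta0)
  -theta0 * log(ea - stats::runif(n) * (ea - eb))
}

#' Sample forward-peaked emission directions
#'
#' The polar angle to the beam axis follows a truncated exponential density
#' `~ exp(-theta / theta0)` on `[0, pi/2]`; the azimuth is uniform. This is
#' the strongly forward-peaked, exponentially falling angular emission of
#' secondary charged fragments.
#'
#' @param n Number of directions.
#' @param model An [emission_model] (only `theta0` is used).
#' @return n x 3 matrix of unit direction vectors (beam along +z).
#' @export
sample_emission_direction <- function(n, model) {
  th <- .sample_theta_band(n, model$theta0, 0, pi / 2)
  ph <- stats::runif(n, 0, 2 * pi)
  cbind(x = sin(th) * cos(ph), y = sin(th) * sin(ph), z = cos(th))
}

## --- fragment transport ----------------------------------------------------

## water-equivalent path integral from points o along unit directions d to
## the phantom boundary (vectorized; o, d are n x 3 matrices)
.path_integral <- function(phantom, o, d) {
  n <- nrow(o)
  eps <- 1e-12
  bounds_lo <- c(-phantom$lateral_half_extent[1],
                 -phantom$lateral_half_extent[2], phantom$entry_z)
  bounds_hi <- c(phantom$lateral_half_extent[1],
                 phantom$lateral_half_extent[2], phantom$exit_z)
  s_exit <- rep(Inf, n)
  for (ax in 1:3) {
    dc <- d[, ax]; oc <- o[, ax]
    s <- rep(Inf, n)
    pos <- dc > eps; neg <- dc < -eps
    s[pos] <- (bounds_hi[ax] - oc[pos]) / dc[pos]
    s[neg] <- (bounds_lo[ax] - oc[neg]) / dc[neg]
    s_exit <- pmin(s_exit, s)
  }
  s_exit[s_exit < 0] <- 0
  dz <- d[, 3]
  z_end <- o[, 3] + dz * s_exit
  base <- numeric(n)
  mov <- abs(dz) > eps
  base[mov] <- (.wed_base(phantom, z_end[mov]) -
                  .wed_base(phantom, o[mov, 3])) / dz[mov]
  if (any(!mov)) {
    base[!mov] <- .rho_base_z(phantom, o[!mov, 3]) * s_exit[!mov]
  }
  base[base < 0] <- 0
  # cavity box contribution: clip the ray to the axis-aligned box
  lo <- c(phantom$cavity_center[1] - phantom$cavity_lateral[1] / 2,
          phantom$cavity_center[2] - phantom$cavity_lateral[2] / 2,
          phantom$cavity_z[1])
  hi <- c(phantom$cavity_center[1] + phantom$cavity_lateral[1] / 2,
          phantom$cavity_center[2] + phantom$cavity_lateral[2] / 2,
          phantom$cavity_z[2])
  s0 <- rep(0, n); s1 <- s_exit
  for (ax in 1:3) {
    dc <- d[, ax]; oc <- o[, ax]
    t0 <- (lo[ax] - oc) / dc
    t1 <- (hi[ax] - oc) / dc
    swap <- which(dc < 0)
    tmp <- t0[swap]; t0[swap] <- t1[swap]; t1[swap] <- tmp
    par <- which(abs(dc) <= eps)
    if (length(par)) {
      inside <- oc[par] >= lo[ax] & oc[par] <= hi[ax]
      t0[par] <- c(Inf, -Inf)[inside + 1L]
      t1[par] <- c(-Inf, Inf)[inside + 1L]
    }
    s0 <- pmax(s0, t0)
    s1 <- pmin(s1, t1)
  }
  L <- pmax(0, s1 - s0)
  hb <- which(L > 0)
  if (length(hb)) {
    zb0 <- o[hb, 3] + dz[hb] * s0[hb]
    zb1 <- o[hb, 3] + dz[hb] * s1[hb]
    movb <- abs(dz[hb]) > eps
    base_in_box <- numeric(length(hb))
    base_in_box[movb] <- (.wed_base(phantom, zb1[movb]) -
                            .wed_base(phantom, zb0[movb])) / dz[hb][movb]
    base_in_box[!movb] <- .rho_base_z(phantom, o[hb[!movb], 3]) * L[hb][!movb]
    base[hb] <- base[hb] + .box_density(phantom) * L[hb] - base_in_box
  }
  base
}

#' Fragment survival probability through the phantom
#'
#' Probability that a fragment emitted at `origin` along `direction` escapes
#' the phantom without being absorbed: `exp(-W / fragment_att_length)` with W
#' the water-equivalent path length from the vertex to the phantom boundary
#' (the cavity/insert is included where traversed).
#'
#' @param origin n x 3 matrix (or length-3 vector) of vertex positions, mm.
#' @param direction n x 3 matrix (or length-3 vector) of unit directions.
#' @param phantom A [phantom_model].
#' @param model An [emission_model].
#' @return Numeric vector of survival probabilities.
#' @export
fragment_survival_prob <- function(origin, direction, phantom, model) {
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 3)
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3)
  exp(-.path_integral(phantom, origin, direction) / model$fragment_att_length)
}

## MCS: perturb unit directions by independent Gaussian transverse deviates
.mcs_perturb <- function(d, sigma) {
  if (sigma <= 0) return(d)
  n <- nrow(d)
  ref <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  steep <- abs(d[, 3]) > 0.9
  ref[steep, ] <- matrix(rep(c(1, 0, 0), each = sum(steep)), ncol = 3)
  e1 <- cbind(d[, 2] * ref[, 3] - d[, 3] * ref[, 2],
              d[, 3] * ref[, 1] - d[, 1] * ref[, 3],
              d[, 1] * ref[, 2] - d[, 2] * ref[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(d[, 2] * e1[, 3] - d[, 3] * e1[, 2],
              d[, 3] * e1[, 1] - d[, 1] * e1[, 3],
              d[, 1] * e1[, 2] - d[, 2] * e1[, 1])
  g1 <- stats::rnorm(n, 0, sigma)
  g2 <- stats::rnorm(n, 0, sigma)
  dn <- d + e1 * g1 + e2 * g2
  dn / sqrt(rowSums(dn^2))
}

#' Transport fragments out of the phantom
#'
#' Applies absorption (Bernoulli survival with probability
#' [fragment_survival_prob]) and multiple-Coulomb-scattering blur (Gaussian
#' transverse angular deviates of `mcs_sigma`) to emitted fragments.
#'
#' @inheritParams fragment_survival_prob
#' @return List with `survived` (logical) and `direction` (n x 3 matrix of
#'   blurred unit directions).
#' @export
transport_fragment <- function(origin, direction, phantom, model) {
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 3)
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3)
  p <- fragment_survival_prob(origin, direction, phantom, model)
  survived <- stats::runif(nrow(origin)) < p
  list(survived = survived,
       direction = .mcs_perturb(direction, model$mcs_sigma))
}

## --- detector response -----------------------------------------------------

#' Two-layer pixel detector response
#'
#' Intersects fragment rays with the two detection layers; rays crossing a
#' layer's active area deposit a lognormally sampled energy that is spread
#' over the four nearest pixels by bilinear charge sharing, and pixels below
#' the per-pixel threshold (3 keV) are dropped. Times of arrival get
#' nanosecond-scale jitter plus per-pixel time walk and are quantized to the
#' 1.5625 ns clock. A fragment counts as detected when it leaves at least one
#' above-threshold pixel in each of the two layers.
#'
#' @param origin n x 3 matrix of ray origins, mm.
#' @param direction n x 3 matrix of unit ray directions.
#' @param t_ns Per-ray emission times, ns.
#' @param geom A [tracker_geometry].
#' @param model An [emission_model] (energy sampler and threshold).
#' @return List with `hits` (a pixel-hit `data.frame` for both layers, see
#'   [read_pixel_hits]), `detected`, `hit_front`, `hit_back` (logicals per
#'   ray) and `frag_idx` attached to each hit row (column `frag`).
#' @export
detector_response <- function(origin, direction, t_ns, geom, model) {
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 3)
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3)
  half <- geom$active_area / 2
  np <- geom$pixels_per_layer
  ints <- list(front = .intersect_layer(origin, direction, geom$layers$front, half),
               back = .intersect_layer(origin, direction, geom$layers$back, half))
  hit_front <- ints$front$hit
  hit_back <- ints$back$hit
  out <- vector("list", 2)
  for (k in 1:2) {
    lid <- c("front", "back")[k]
    it <- ints[[lid]]
    idx <- which(it$hit)
    if (length(idx) == 0) next
    colf <- it$u1[idx] / geom$pixel_pitch + (np[1] - 1) / 2
    rowf <- it$u2[idx] / geom$pixel_pitch + (np[2] - 1) / 2
    e_tot <- stats::rlnorm(length(idx), log(model$edep_median), model$edep_sdlog)
    t_lay <- t_ns[idx] + stats::rnorm(length(idx), 0, 1.5)
    c0 <- floor(colf); a <- colf - c0
    r0 <- floor(rowf); b <- rowf - r0
    w <- cbind((1 - a) * (1 - b), a * (1 - b), (1 - a) * b, a * b)
    pc <- cbind(c0, c0 + 1, c0, c0 + 1)
    pr <- cbind(r0, r0, r0 + 1, r0 + 1)
    nh <- length(idx)
    hit_col <- as.vector(pc)
    hit_row <- as.vector(pr)
    hit_e <- as.vector(w) * rep(e_tot, 4)
    hit_t <- rep(t_lay, 4) + abs(stats::rnorm(4 * nh, 0, 2))
    hit_frag <- rep(idx, 4)
    keep <- hit_e >= model$threshold_kev &
      hit_col >= 0 & hit_col < np[1] & hit_row >= 0 & hit_row < np[2]
    if (!any(keep)) next
    out[[k]] <- data.frame(
      layer = rep(lid, sum(keep)),
      chip = ifelse(hit_col[keep] < np[1] / 2, 0L, 1L),
      col = as.integer(hit_col[keep]),
      row = as.integer(hit_row[keep]),
      toa_ns = quantize_toa(hit_t[keep]),
      energy_kev = hit_e[keep],
      frag = hit_frag[keep]
    )
  }
  hits <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(hits)) {
    hits <- data.frame(layer = character(), chip = integer(), col = integer(),
                       row = integer(), toa_ns = numeric(),
                       energy_kev = numeric(), frag = integer())
  }
  # detection demands an above-threshold pixel in each layer
  det_f <- det_b <- rep(FALSE, nrow(origin))
  det_f[unique(hits$frag[hits$layer == "front"])] <- TRUE
  det_b[unique(hits$frag[hits$layer == "back"])] <- TRUE
  list(hits = hits, detected = det_f & det_b,
       hit_front = hit_front, hit_back = hit_back)
}

## --- acceptance band -------------------------------------------------------

## Conservative (theta, phi) emission band toward the tracker: the smallest
## angular box, over a lateral rectangle of possible vertex positions and the
## depth grid z, that contains every direction able to intersect a layer
## corner, padded by an angular margin covering the scattering blur (at more
## than 5 sigma). theta limits are per depth bin; phi limits are depth
## independent (pencil beams run along z).
.band_from_rect <- function(z, xr, yr, geom, ang_margin) {
  half <- geom$active_area / 2
  corners <- matrix(0, 8, 3)
  k <- 0
  for (lid in c("front", "back")) {
    lay <- geom$layers[[lid]]
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
      k <- k + 1
      corners[k, ] <- lay$center + s1 * half[1] * lay$e1 + s2 * half[2] * lay$e2
    }
  }
  nz <- length(z)
  theta_lo <- rep(Inf, nz); theta_hi <- rep(-Inf, nz)
  phi_lo <- Inf; phi_hi <- -Inf
  for (vx in xr) for (vy in yr) {
    dx <- corners[, 1] - vx
    dy <- corners[, 2] - vy
    rho <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    phi_lo <- min(phi_lo, phi); phi_hi <- max(phi_hi, phi)
    # theta of each corner as seen from each depth: outer over (z, corner)
    th <- atan2(matrix(rho, nz, 8, byrow = TRUE),
                outer(-z, corners[, 3], "+"))
    theta_lo <- pmin(theta_lo, apply(th, 1, min))
    theta_hi <- pmax(theta_hi, apply(th, 1, max))
  }
  list(theta_lo = pmax(theta_lo - ang_margin, 0),
       theta_hi = pmin(theta_hi + ang_margin, pi / 2),
       phi_c = (phi_lo + phi_hi) / 2,
       d_phi = (phi_hi - phi_lo) / 2 + ang_margin)
}

## Bands for every unique spot lateral position (non-crossing primaries: the
## vertex lies within 5 sigma of the nominal spot) and a single band for
## crossing primaries (the vertex lies inside the cavity box laterally).
.precompute_bands <- function(beam_log, z, phantom, geom, model) {
  ang_margin <- 5 * model$mcs_sigma + 0.01
  # lateral beam spread is taken from the delivery log (per spot); the band
  # must cover the widest one
  m <- 5 * max(beam_log$sigma_mm, 1e-6)
  key <- paste(beam_log$x_mm, beam_log$y_mm)
  uk <- !duplicated(key)
  nocross <- list()
  for (i in which(uk)) {
    sx <- beam_log$x_mm[i]; sy <- beam_log$y_mm[i]
    nocross[[key[i]]] <- .band_from_rect(z, c(sx - m, sx + m),
                                         c(sy - m, sy + m), geom, ang_margin)
  }
  bx <- phantom$cavity_center[1] + c(-1, 1) * phantom$cavity_lateral[1] / 2
  by <- phantom$cavity_center[2] + c(-1, 1) * phantom$cavity_lateral[2] / 2
  list(nocross = nocross,
       cross = .band_from_rect(z, bx, by, geom, ang_margin))
}

## --- lateral sampling ------------------------------------------------------

## truncated normal via inverse CDF
.rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## sample n lateral positions of one spot conditioned on crossing (inside the
## cavity box laterally) or not crossing
.sample_lateral <- function(n, spot_x, spot_y, sigma, phantom, crossing) {
  bx <- phantom$cavity_center[1] + c(-1, 1) * phantom$cavity_lateral[1] / 2
  by <- phantom$cavity_center[2] + c(-1, 1) * phantom$cavity_lateral[2] / 2
  px <- stats::pnorm(bx[2], spot_x, sigma) - stats::pnorm(bx[1], spot_x, sigma)
  py <- stats::pnorm(by[2], spot_y, sigma) - stats::pnorm(by[1], spot_y, sigma)
  if (crossing) {
    return(cbind(.rtnorm(n, spot_x, sigma, bx[1], bx[2]),
                 .rtnorm(n, spot_y, sigma, by[1], by[2])))
  }
  # complement: x outside; or x inside and y outside
  p_out <- c(1 - px, px * (1 - py))
  pick <- sample.int(2, n, replace = TRUE, prob = p_out)
  x <- numeric(n); y <- numeric(n)
  n1 <- sum(pick == 1)
  if (n1 > 0) {
    # x outside the box interval: mixture of the two tails
    p_left <- stats::pnorm(bx[1], spot_x, sigma)
    p_right <- 1 - stats::pnorm(bx[2], spot_x, sigma)
    left <- stats::runif(n1) < p_left / (p_left + p_right)
    xs <- numeric(n1)
    xs[left] <- .rtnorm(sum(left), spot_x, sigma, -Inf, bx[1])
    xs[!left] <- .rtnorm(sum(!left), spot_x, sigma, bx[2], Inf)
    x[pick == 1] <- xs
    y[pick == 1] <- stats::rnorm(n1, spot_y, sigma)
  }
  n2 <- sum(pick == 2)
  if (n2 > 0) {
    x[pick == 2] <- .rtnorm(n2, spot_x, sigma, bx[1], bx[2])
    p_left <- stats::pnorm(by[1], spot_y, sigma)
    p_right <- 1 - stats::pnorm(by[2], spot_y, sigma)
    left <- stats::runif(n2) < p_left / (p_left + p_right)
    ys <- numeric(n2)
    ys[left] <- .rtnorm(sum(left), spot_y, sigma, -Inf, by[1])
    ys[!left] <- .rtnorm(sum(!left), spot_y, sigma, by[2], Inf)
    y[pick == 2] <- ys
  }
  cbind(x, y)
}

## probability that a primary of one spot crosses the cavity box laterally
.p_cross <- function(spot_x, spot_y, sigma, phantom) {
  bx <- phantom$cavity_center[1] + c(-1, 1) * phantom$cavity_lateral[1] / 2
  by <- phantom$cavity_center[2] + c(-1, 1) * phantom$cavity_lateral[2] / 2
  (stats::pnorm(bx[2], spot_x, sigma) - stats::pnorm(bx[1], spot_x, sigma)) *
    (stats::pnorm(by[2], spot_y, sigma) - stats::pnorm(by[1], spot_y, sigma))
}

## --- full acquisition ------------------------------------------------------

#' Primaries per spot for a full-statistics ("signature-scale") acquisition
#'
#' The scaled default plan (2000 primaries per spot) keeps routine tests
#' fast; detecting the few-percent absorption deficits of a realistic
#' density change requires the counting statistics of a clinical acquisition
#' (about 2e6 detected fragments in a summed reference run, i.e. of order
#' 1e4 counts in the populated voxels). This constant is the per-spot
#' primary count that reaches that regime with the default plan layout.
#'
#' @export
signature_primaries <- 150000

#' Simulate one monitored treatment fraction
#'
#' Runs the full generator: for each repetition of the delivered plan,
#' fragmentation vertices are produced along each pencil beam (depth from the
#' production density, lateral position from the beam spread, cavity handled
#' exactly for crossing and non-crossing primaries), fragments are emitted
#' forward-peaked, transported out of the phantom with absorption and
#' scattering, and registered by the two-layer pixel detector. Repetitions
#' emulate a larger monitoring system of several trackers and use independent
#' random substreams; their summed fragment distributions are compared
#' downstream.
#'
#' @param plan Plan from [generate_plan]; default plan if `NULL`.
#' @param phantom A [phantom_model].
#' @param geom A [tracker_geometry].
#' @param model An [emission_model].
#' @param n_repetitions Number of repeated deliveries (default 7).
#' @param seed Master seed; every repetition derives its own substream.
#' @param n_primaries Optional override of the plan's primaries per spot.
#' @return Object of class `sim_output`: `repetitions` (per repetition a
#'   list with `hits_front`, `hits_back`, `truth` — true vertices of the
#'   detected fragments), `beam_log`, `stats` (produced / in-band / detected
#'   counters) and `provenance`.
#' @export
simulate_fraction <- function(plan = NULL,
                              phantom = phantom_model(),
                              geom = tracker_geometry(),
                              model = emission_model(),
                              n_repetitions = 7,
                              seed = 1,
                              n_primaries = NULL) {
  if (is.null(plan)) plan <- generate_plan()
  beam_log <- plan$beam_log
  if (!is.null(n_primaries)) {
    scale <- n_primaries / beam_log$n_primaries[1]
    beam_log$n_primaries <- n_primaries
    dur <- (beam_log$t_end_ns - beam_log$t_start_ns) * scale
    gap <- 0.1 * dur + 1000
    beam_log$t_start_ns <- cumsum(c(0, (dur + gap)[-nrow(beam_log)]))
    beam_log$t_end_ns <- beam_log$t_start_ns + dur
  }
  energies <- unique(beam_log$energy_mev_u)
  zgrid <- .depth_grid(phantom, model, energies[1], crossing = FALSE)$z
  bands <- .precompute_bands(beam_log, zgrid, phantom, geom, model)
  reps <- vector("list", n_repetitions)
  stats_tot <- c(n_produced = 0, n_inband = 0, n_detected = 0)
  for (r in seq_len(n_repetitions)) {
    set.seed((seed + 7919L * r) %% .Machine$integer.max)
    rep_out <- .simulate_repetition(beam_log, energies, phantom, geom, model,
                                    bands, frag_id_base = r * 1e8)
    reps[[r]] <- rep_out[c("hits_front", "hits_back", "truth")]
    stats_tot <- stats_tot + rep_out$stats
  }
  structure(list(repetitions = reps, beam_log = beam_log, stats = stats_tot,
                 provenance = list(seed = seed, n_repetitions = n_repetitions,
                                   insert = phantom$insert,
                                   n_primaries = beam_log$n_primaries[1],
                                   n_spots = nrow(beam_log))),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %d repetitions, %d spots x %d primaries, insert %s\n",
              length(x$repetitions), x$provenance$n_spots,
              x$provenance$n_primaries,
              if (x$provenance$insert) "on" else "off"))
  cat(sprintf("  fragments: %.3g produced, %.3g simulated toward tracker, %d detected\n",
              x$stats["n_produced"], x$stats["n_inband"],
              as.integer(x$stats["n_detected"])))
  invisible(x)
}

## one repetition of the delivered plan
.simulate_repetition <- function(beam_log, energies, phantom, geom, model,
                                 bands, frag_id_base = 0) {
  hit_cols <- c("layer", "chip", "col", "row", "toa_ns", "energy_kev")
  truth_cols <- c("frag_id", "x", "y", "z", "spot_id", "t_ns")
  hits_acc <- list()
  truth_acc <- list()
  n_prod <- 0; n_ib <- 0; n_det <- 0
  frag_counter <- 0
  for (energy in energies) {
    spots <- beam_log[beam_log$energy_mev_u == energy, , drop = FALSE]
    grids <- list(cross = .depth_grid(phantom, model, energy, crossing = TRUE),
                  nocross = .depth_grid(phantom, model, energy, crossing = FALSE))
    frag <- .generate_layer_fragments(spots, grids, phantom, model, bands)
    v <- frag$vertices
    nf <- length(v$x)
    n_prod <- n_prod + frag$n_produced
    n_ib <- n_ib + nf
    if (nf == 0) next
    o <- cbind(v$x, v$y, v$z)
    st <- sin(v$theta)
    d <- cbind(st * cos(v$phi), st * sin(v$phi), cos(v$theta))
    tr <- transport_fragment(o, d, phantom, model)
    alive <- tr$survived
    if (!any(alive)) next
    det <- detector_response(o[alive, , drop = FALSE],
                             tr$direction[alive, , drop = FALSE],
                             v$t_ns[alive], geom, model)
    # keep hits of fragments seen in both layers (detected) plus single-layer
    # background; fragment ids are only recorded for detected fragments
    alive_idx <- which(alive)
    det_global <- alive_idx[det$detected]
    if (length(det_global) > 0) {
      ids <- frag_id_base + frag_counter + seq_along(det_global)
      truth_acc[[length(truth_acc) + 1]] <- list(
        frag_id = ids,
        x = v$x[det_global], y = v$y[det_global], z = v$z[det_global],
        spot_id = v$spot_id[det_global],
        t_ns = v$t_ns[det_global]
      )
      frag_counter <- frag_counter + length(det_global)
      n_det <- n_det + length(det_global)
    }
    hits_acc[[length(hits_acc) + 1]] <- det$hits[hit_cols]
  }
  hits <- if (length(hits_acc)) {
    cols <- lapply(hit_cols,
                   function(f) unlist(lapply(hits_acc, `[[`, f),
                                      use.names = FALSE))
    names(cols) <- hit_cols
    as.data.frame(cols)
  } else {
    data.frame(layer = character(), chip = integer(), col = integer(),
               row = integer(), toa_ns = numeric(), energy_kev = numeric())
  }
  hits <- hits[order(hits$toa_ns), , drop = FALSE]
  rownames(hits) <- NULL
  truth <- if (length(truth_acc)) {
    cols <- lapply(truth_cols,
                   function(f) unlist(lapply(truth_acc, `[[`, f),
                                      use.names = FALSE))
    names(cols) <- truth_cols
    tr <- as.data.frame(cols)
    tr$detected <- TRUE
    tr
  } else {
    data.frame(frag_id = numeric(), x = numeric(), y = numeric(),
               z = numeric(), spot_id = integer(), t_ns = numeric(),
               detected = logical())
  }
  front <- hits$layer == "front"
  list(hits_front = hits[front, , drop = FALSE],
       hits_back = hits[!front, , drop = FALSE],
       truth = truth,
       stats = c(n_produced = n_prod, n_inband = n_ib, n_detected = n_det))
}

## generate the in-band fragment population of one energy layer
.generate_layer_fragments <- function(spots, grids, phantom, model, bands) {
  acc <- list()
  n_produced <- 0
  for (s in seq_len(nrow(spots))) {
    sx <- spots$x_mm[s]; sy <- spots$y_mm[s]
    sig <- spots$sigma_mm[s]
    npr <- spots$n_primaries[s]
    pc <- .p_cross(sx, sy, sig, phantom)
    for (cls in c("cross", "nocross")) {
      p_class <- if (cls == "cross") pc else 1 - pc
      if (p_class < 1e-12) next
      g <- grids[[cls]]
      band <- if (cls == "cross") bands$cross else
        bands$nocross[[paste(sx, sy)]]
      p_theta <- .p_theta_band(model$theta0, band$theta_lo, band$theta_hi)
      p_band_z <- p_theta * (2 * band$d_phi) / (2 * pi)
      lambda_ib <- npr * p_class * sum(g$f * p_band_z) * g$dz
      lambda_tot <- npr * p_class * g$yield
      n_produced <- n_produced + stats::rpois(1, max(lambda_tot - lambda_ib, 0))
      n <- stats::rpois(1, lambda_ib)
      n_produced <- n_produced + n
      if (n == 0) next
      bin <- sample.int(length(g$z), n, replace = TRUE, prob = g$f * p_band_z)
      z <- g$z[bin] + stats::runif(n, -g$dz / 2, g$dz / 2)
      theta <- .sample_theta_band(n, model$theta0,
                                  band$theta_lo[bin], band$theta_hi[bin])
      phi <- band$phi_c + stats::runif(n, -band$d_phi, band$d_phi)
      lat <- .sample_lateral(n, sx, sy, sig, phantom, cls == "cross")
      acc[[length(acc) + 1]] <- list(
        x = lat[, 1], y = lat[, 2], z = z, theta = theta, phi = phi,
        t_ns = stats::runif(n, spots$t_start_ns[s], spots$t_end_ns[s]),
        spot_id = rep(spots$spot_id[s], n)
      )
    }
  }
  vertices <- if (length(acc)) {
    cols <- lapply(c("x", "y", "z", "theta", "phi", "t_ns", "spot_id"),
                   function(f) unlist(lapply(acc, `[[`, f), use.names = FALSE))
    names(cols) <- c("x", "y", "z", "theta", "phi", "t_ns", "spot_id")
    cols
  } else {
    list(x = numeric(), y = numeric(), z = numeric(), theta = numeric(),
         phi = numeric(), t_ns = numeric(), spot_id = integer())
  }
  list(vertices = vertices, n_produced = n_produced)
}
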