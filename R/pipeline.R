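#' Run the reconstruction chain on one acquisition
#'
#' Orchestrates clustering, coincidence matching, track building, beam
#' association and midpoint-projection vertexing for one repetition's hit
#' data, and returns the vertex table together with a run report of
#' per-stage counts.
#'
#' @param hits_front,hits_back Hit `data.frame`s (see [read_pixel_hits]) or
#'   paths to hit TSV files.
#' @param beam_log Beam-record `data.frame` or path to a beam-log TSV.
#' @param geom A [tracker_geometry].
#' @param config Configuration list (see [default_config]); clustering and
#'   tracking blocks are used.
#' @return List of class `reco_result`: `vertices`, `tracks`, `report` (a
#'   `run_report` with stage counts and warnings).
#' @export
run_reconstruction <- function(hits_front, hits_back, beam_log,
                               geom = tracker_geometry(),
                               config = default_config()) {
  if (is.character(hits_front)) hits_front <- read_pixel_hits(hits_front)
  if (is.character(hits_back)) hits_back <- read_pixel_hits(hits_back)
  if (is.character(beam_log)) beam_log <- read_beam_log(beam_log)
  warnings <- character()
  cl_f <- cluster_hits(hits_front, config$clustering$time_window_ns,
                       config$clustering$adjacency)
  cl_b <- cluster_hits(hits_back, config$clustering$time_window_ns,
                       config$clustering$adjacency)
  if (nrow(cl_f) > 0 && nrow(cl_b) == 0) {
    warnings <- c(warnings, "no back-layer clusters: zero tracks")
  }
  if (nrow(cl_b) > 0 && nrow(cl_f) == 0) {
    warnings <- c(warnings, "no front-layer clusters: zero tracks")
  }
  mt <- match_coincidences(cl_f, cl_b, config$tracking$window_ns)
  tracks <- build_tracks(cl_f, cl_b, mt, geom)
  vertices <- reconstruct_vertices(tracks, beam_log)
  qc <- attr(vertices, "qc")
  report <- structure(list(
    counts = c(hits_front = nrow(hits_front), hits_back = nrow(hits_back),
               clusters_front = nrow(cl_f), clusters_back = nrow(cl_b),
               matched_pairs = nrow(mt$pairs), tracks = nrow(tracks),
               tracks_no_beam = unname(qc["no_beam"]),
               tracks_degenerate = unname(qc["degenerate"]),
               vertices = nrow(vertices)),
    warnings = warnings), class = "run_report")
  structure(list(vertices = vertices, tracks = tracks, report = report),
            class = "reco_result")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
print.reco_result <- function(x, ...) {
  cat(sprintf("<reco_result> %d vertices from %d tracks\n",
              nrow(x$vertices), x$report$counts[["tracks"]]))
  invisible(x)
}

#' Reconstruct and sum all repetitions of a simulated acquisition
#'
#' Convenience wrapper: runs [run_reconstruction] on every repetition of a
#' [simulate_fraction] output and concatenates the vertex tables (the summed
#' distributions emulate a multi-tracker monitoring system).
#'
#' @param sim A `sim_output`.
#' @inheritParams run_reconstruction
#' @return List with `vertices` (all repetitions), `truth` (all
#'   repetitions), and `reports` (per repetition).
#' @export
reconstruct_all <- function(sim, geom = tracker_geometry(),
                            config = default_config()) {
  stopifnot(inherits(sim, "sim_output"))
  verts <- list(); truths <- list(); reports <- list()
  for (r in seq_along(sim$repetitions)) {
    rr <- sim$repetitions[[r]]
    reco <- run_reconstruction(rr$hits_front, rr$hits_back, sim$beam_log,
                               geom, config)
    v <- link_truth(reco$vertices, rr$truth)
    v$repetition <- r
    verts[[r]] <- v
    truths[[r]] <- rr$truth
    reports[[r]] <- reco$report
  }
  list(vertices = do.call(rbind, verts),
       truth = do.call(rbind, truths),
       reports = reports)
}

#' Compare two fragment distributions
#'
#' Voxelizes two vertex collections on the same grid, computes the
#' difference map with the Poisson significance threshold, the
#' expected-by-chance exceedance count, depth profiles and their
#' region-integrated differences.
#'
#' @param vertices_ref,vertices_test Vertex `data.frame`s (columns `x`, `y`,
#'   `z`), e.g. from [reconstruct_all]; reference is distribution 1.
#' @param config Configuration list (grid and regions blocks are used).
#' @param chance_draws Monte Carlo replicates per voxel for the chance
#'   calibration (0 skips it).
#' @return List of class `comparison_result`: `dist_ref`, `dist_test`, `map`
#'   ([difference_map]), `significant` (from [count_significant]),
#'   `expected_chance`, `profiles` (ref/test [depth_profile]s),
#'   `region_deltas` (named per region).
#' @export
run_comparison <- function(vertices_ref, vertices_test,
                           config = default_config(), chance_draws = 2000) {
  g <- config$grid
  grid <- grid_spec(g$origin, g$voxel_size, g$shape)
  d1 <- voxelize(vertices_ref, grid)
  d2 <- voxelize(vertices_test, grid)
  map <- difference_map(d1, d2, min_count = g$min_count, k_sigma = g$k_sigma)
  sig <- count_significant(map)
  chance <- if (chance_draws > 0 && any(map$eligible)) {
    expected_chance_exceedances(as.numeric(d1$counts[map$eligible]),
                                k_sigma = g$k_sigma, n_draws = chance_draws)
  } else NULL
  regions <- config$regions
  p1 <- depth_profile(vertices_ref, regions = regions)
  p2 <- depth_profile(vertices_test, regions = regions)
  deltas <- vapply(regions, function(r) region_delta(p1, p2, r), 0)
  structure(list(dist_ref = d1, dist_test = d2, map = map,
                 significant = sig, expected_chance = chance,
                 profiles = list(ref = p1, test = p2),
                 region_deltas = deltas),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  cat(sprintf("  vertices: %d (ref) vs %d (test) in grid\n",
              x$dist_ref$n_total_in_grid, x$dist_test$n_total_in_grid))
  cat(sprintf("  eligible voxels: %d; significant: %d",
              sum(x$map$eligible), x$significant$n))
  if (!is.null(x$expected_chance)) {
    cat(sprintf(" (%.1f expected by chance)", x$expected_chance$expected))
  }
  cat("\n  region count changes (test - ref):\n")
  for (nm in names(x$region_deltas)) {
    cat(sprintf("    %-12s %+.0f\n", nm, x$region_deltas[[nm]]))
  }
  invisible(x)
}

#' Split significant voxels relative to a z-interval
#'
#' Helper for signature analysis: classifies the significant voxels of a
#' comparison by the position of their centers relative to a z-interval
#' (e.g. the cavity), separately for deficits (fewer counts in the test
#' distribution) and excesses.
#'
#' @param comparison A `comparison_result`.
#' @param z_interval Length-2 z-interval, mm.
#' @return List of counts: `deficit_upstream`, `deficit_inside`,
#'   `deficit_downstream`, `excess_upstream`, `excess_inside`,
#'   `excess_downstream`.
#' @export
signature_split <- function(comparison, z_interval) {
  vox <- comparison$significant$voxels
  up <- vox$z < z_interval[1]
  down <- vox$z > z_interval[2]
  inside <- !up & !down
  list(deficit_upstream = sum(up & vox$delta < 0),
       deficit_inside = sum(inside & vox$delta < 0),
       deficit_downstream = sum(down & vox$delta < 0),
       excess_upstream = sum(up & vox$delta > 0),
       excess_inside = sum(inside & vox$delta > 0),
       excess_downstream = sum(down & vox$delta > 0))
}
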