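## Plain-text file dialects
##
## Pixel hits:  TSV, header "layer chip col row toa_ns energy_kev".
## Beam log:    TSV, header "spot_id energy_mev_u x_mm y_mm sigma_mm
##              n_primaries t_start_ns t_end_ns".
## Voxel grids: TSV of (ix iy iz count) for non-empty voxels plus a JSON
##              sidecar with the grid origin, voxel size, shape and totals.
## The real Timepix3 readout stream is proprietary; these dialects are the
## package's interchange formats and double as human-diffable test fixtures.

#' Timepix3 time-of-arrival quantum, ns
#'
#' All times of arrival are integer multiples of this quantum (1.5625 ns).
#' @export
TOA_QUANTUM_NS <- 1.5625

#' Quantize times to the ToA clock
#'
#' @param t_ns Numeric times, ns.
#' @return Times rounded to the nearest multiple of [TOA_QUANTUM_NS].
#' @export
quantize_toa <- function(t_ns) round(t_ns / TOA_QUANTUM_NS) * TOA_QUANTUM_NS

.hit_cols <- c("layer", "chip", "col", "row", "toa_ns", "energy_kev")
.beam_cols <- c("spot_id", "energy_mev_u", "x_mm", "y_mm", "sigma_mm",
                "n_primaries", "t_start_ns", "t_end_ns")

#' Read a pixel-hit list
#'
#' Reads a TSV hit list (one row per pixel signal: detection layer, readout
#' chip, pixel column/row, time of arrival, deposited energy) and validates
#' it. Hits are returned sorted by time of arrival.
#'
#' @param path Path to a TSV file with columns
#'   `layer chip col row toa_ns energy_kev`.
#' @return A `data.frame` of hits, ordered by `toa_ns`.
#' @export
read_pixel_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(.hit_cols %in% names(df))) {
    stop("hit file ", path, " is missing column(s): ",
         paste(setdiff(.hit_cols, names(df)), collapse = ", "))
  }
  df <- df[.hit_cols]
  if (nrow(df) == 0) return(df)
  for (cn in c("chip", "col", "row", "toa_ns", "energy_kev")) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop(sprintf("malformed value in column '%s' at data row %d of %s",
                   cn, bad, path))
    }
  }
  if (any(bad <- !(df$layer %in% c("front", "back")))) {
    stop(sprintf("invalid layer at data row %d of %s", which(bad)[1], path))
  }
  if (any(bad <- df$energy_kev <= 0)) {
    stop(sprintf("non-positive energy at data row %d of %s",
                 which(bad)[1], path))
  }
  if (any(bad <- df$toa_ns < 0)) {
    stop(sprintf("negative time of arrival at data row %d of %s",
                 which(bad)[1], path))
  }
  for (cn in c("chip", "col", "row")) df[[cn]] <- as.integer(df[[cn]])
  for (cn in c("toa_ns", "energy_kev")) df[[cn]] <- as.numeric(df[[cn]])
  df <- df[order(df$toa_ns), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a pixel-hit list
#'
#' @param hits Hit `data.frame` (see [read_pixel_hits]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pixel_hits <- function(hits, path) {
  stopifnot(is.data.frame(hits), all(.hit_cols %in% names(hits)))
  utils::write.table(format(hits[.hit_cols], digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pencil-beam delivery log
#'
#' One row per delivered spot: nominal lateral position at the isocenter,
#' beam energy, focus size, number of primaries and the delivery time
#' interval. Records must be time-ordered and non-overlapping, as produced by
#' the beam application and monitoring system.
#'
#' @param path TSV path with columns `spot_id energy_mev_u x_mm y_mm sigma_mm
#'   n_primaries t_start_ns t_end_ns`.
#' @param energy_range Soft validation range for beam energies (MeV/u); a
#'   warning is issued for records outside it (the record is kept). Use `NULL`
#'   to skip.
#' @return A `data.frame` of beam records ordered by `t_start_ns`.
#' @export
read_beam_log <- function(path, energy_range = c(153, 250)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(.beam_cols %in% names(df))) {
    stop("beam log ", path, " is missing column(s): ",
         paste(setdiff(.beam_cols, names(df)), collapse = ", "))
  }
  df <- df[.beam_cols]
  if (nrow(df) == 0) return(df)
  if (any(df$t_start_ns >= df$t_end_ns)) stop("beam record with t_start >= t_end")
  for (cn in c("spot_id", "n_primaries")) df[[cn]] <- as.integer(df[[cn]])
  for (cn in c("energy_mev_u", "x_mm", "y_mm", "sigma_mm", "t_start_ns",
               "t_end_ns")) df[[cn]] <- as.numeric(df[[cn]])
  df <- df[order(df$t_start_ns), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1 && any(df$t_start_ns[-1] < df$t_end_ns[-nrow(df)])) {
    stop("overlapping delivery intervals in beam log")
  }
  if (!is.null(energy_range) &&
      any(df$energy_mev_u < energy_range[1] | df$energy_mev_u > energy_range[2])) {
    warning("beam log contains energies outside [",
            energy_range[1], ", ", energy_range[2], "] MeV/u")
  }
  df
}

#' Write a pencil-beam delivery log
#'
#' @param beam_log Beam-record `data.frame` (see [read_beam_log]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_beam_log <- function(beam_log, path) {
  stopifnot(is.data.frame(beam_log), all(.beam_cols %in% names(beam_log)))
  utils::write.table(format(beam_log[.beam_cols], digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a voxelized fragment distribution
#'
#' Writes the non-empty voxels as a TSV of `(ix, iy, iz, count)` (0-based
#' indices) plus a JSON sidecar (`<path>.json`) carrying the grid origin,
#' voxel size, shape and the in-grid/outside totals.
#'
#' @param dist A `fragment_distribution` (see [voxelize]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "fragment_distribution"))
  idx <- which(dist$counts > 0, arr.ind = TRUE)
  df <- data.frame(ix = idx[, 1] - 1L, iy = idx[, 2] - 1L, iz = idx[, 3] - 1L,
                   count = dist$counts[idx])
  df <- df[order(df$ix, df$iy, df$iz), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(origin = unname(dist$grid$origin),
               voxel_size = unname(dist$grid$voxel_size),
               shape = unname(dist$grid$shape),
               n_total_in_grid = dist$n_total_in_grid,
               n_outside = dist$n_outside)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a voxelized fragment distribution
#'
#' @param path TSV path written by [write_distribution] (the JSON sidecar
#'   `<path>.json` must be present).
#' @return A `fragment_distribution`.
#' @export
read_distribution <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path)) {
    stop("distribution file or JSON sidecar missing for ", path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  grid <- grid_spec(origin = meta$origin, voxel_size = meta$voxel_size,
                    shape = meta$shape)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  counts <- array(0L, dim = grid$shape)
  if (nrow(df) > 0) {
    counts[cbind(df$ix + 1L, df$iy + 1L, df$iz + 1L)] <- as.integer(df$count)
  }
  structure(list(grid = grid, counts = counts,
                 n_total_in_grid = meta$n_total_in_grid,
                 n_outside = meta$n_outside),
            class = "fragment_distribution")
}

#' Default run configuration
#'
#' Returns the full nested configuration used across the pipeline, with every
#' block at its default: tracker geometry, clustering (intra-cluster time
#' window, pixel adjacency), tracking (front/back coincidence window, 75 ns),
#' comparison grid (8 x 8 x 10 mm voxels, eligibility above 100 counts, 2
#' sigma threshold) and the synthetic generator block (phantom, plan, emission
#' model, 7 repetitions).
#'
#' @return Nested list of configuration blocks.
#' @export
default_config <- function() {
  list(
    geometry = list(layer_separation = 20.3, pixel_pitch = 0.055,
                    active_area = c(28, 14), sensor_thickness = 0.5,
                    focus_angle_deg = 30, front_layer_distance = 167,
                    tilt_deg = 1.6, azimuth_deg = 90),
    clustering = list(time_window_ns = 100, adjacency = "8-connected"),
    tracking = list(window_ns = 75),
    grid = list(origin = c(-40, -40, -80), voxel_size = c(8, 8, 10),
                shape = c(10, 10, 16), min_count = 100, k_sigma = 2),
    regions = list(phantom = c(-80, 80), ptv = c(-23, 23),
                   nasopharynx = c(-15, -5)),
    synthetic = list(n_layers = 5, spots_per_layer = 40, n_primaries = 2000,
                     n_repetitions = 7, seed = 1)
  )
}

#' Read / write a run configuration
#'
#' JSON round-trip of the nested configuration list. Missing blocks are
#' filled from [default_config]; unknown top-level blocks are an error.
#'
#' @param path JSON path.
#' @return For `read_config`, the configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- default_config()
  extra <- setdiff(names(cfg), names(def))
  if (length(extra)) stop("unknown config block(s): ", paste(extra, collapse = ", "))
  for (blk in names(def)) {
    if (is.null(cfg[[blk]])) cfg[[blk]] <- def[[blk]]
    else for (k in setdiff(names(def[[blk]]), names(cfg[[blk]]))) {
      cfg[[blk]][[k]] <- def[[blk]][[k]]
    }
  }
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
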