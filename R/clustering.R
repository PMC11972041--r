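#' Cluster coincident neighboring pixel hits
#'
#' Charge sharing spreads the energy deposited by one particle over several
#' neighboring pixels, so coincident neighboring pixel signals must be merged
#' into clusters before tracking. Two hits belong to the same cluster when
#' they are connected by a chain of pixel-adjacent pairs whose times of
#' arrival differ by at most `time_window`. Per cluster: the timestamp is the
#' earliest constituent time of arrival, the energy is the sum of the
#' constituent energies, and the 2D position is the energy-weighted mean of
#' the constituent pixel positions.
#'
#' All hits must come from a single detection layer (the two readout chips of
#' a layer share one sensor, columns are continuous across the chip boundary).
#'
#' @param hits Hit `data.frame` with columns `col`, `row`, `toa_ns`,
#'   `energy_kev` (see [read_pixel_hits]); a `layer` column, if present, must
#'   hold a single value.
#' @param time_window Intra-cluster coincidence window, ns (default 100; must
#'   exceed the per-pixel time-of-arrival walk).
#' @param adjacency `"8-connected"` (default; diagonal charge sharing counts)
#'   or `"4-connected"`.
#' @return A `data.frame` of clusters with columns `layer`, `t_ns`,
#'   `energy_kev`, `centroid_col`, `centroid_row`, `n_pixels`, ordered by
#'   `t_ns`. The attribute `"membership"` maps each input hit (in input order)
#'   to its cluster's row.
#' @export
cluster_hits <- function(hits, time_window = 100,
                         adjacency = c("8-connected", "4-connected")) {
  adjacency <- match.arg(adjacency)
  stopifnot(is.data.frame(hits), time_window > 0)
  layer <- if ("layer" %in% names(hits) && nrow(hits) > 0) {
    u <- unique(hits$layer)
    if (length(u) > 1) stop("cluster_hits expects hits from a single layer")
    u
  } else NA_character_
  empty <- data.frame(layer = character(), t_ns = numeric(),
                      energy_kev = numeric(), centroid_col = numeric(),
                      centroid_row = numeric(), n_pixels = integer())
  if (nrow(hits) == 0) {
    attr(empty, "membership") <- integer()
    return(empty)
  }
  id <- cluster_hits_cpp(as.integer(hits$col), as.integer(hits$row),
                         as.numeric(hits$toa_ns), time_window,
                         adjacency == "8-connected")
  e <- hits$energy_kev
  esum <- as.numeric(rowsum(e, id))
  out <- data.frame(
    layer = layer,
    t_ns = as.numeric(tapply(hits$toa_ns, id, min)),
    energy_kev = esum,
    centroid_col = as.numeric(rowsum(e * hits$col, id)) / esum,
    centroid_row = as.numeric(rowsum(e * hits$row, id)) / esum,
    n_pixels = as.integer(tabulate(id))
  )
  ord <- order(out$t_ns, out$centroid_col, out$centroid_row)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "membership") <- match(id, ord)
  out
}
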