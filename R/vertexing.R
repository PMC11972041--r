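#' Associate tracks with the pencil beam delivered at their timestamp
#'
#' Scanned delivery irradiates one spot at a time, so a track's front-layer
#' timestamp identifies the pencil beam that produced the fragment. The
#' delivery interval is treated as closed, `[t_start, t_end]`; timestamps in
#' inter-spot gaps are left unassigned (conservative: projecting onto the
#' wrong beam line is worse than dropping a track), and such tracks are
#' excluded from vertexing and counted in the run report.
#'
#' @param t_track Numeric vector of track timestamps, ns.
#' @param beam_log Beam-record `data.frame` (see [read_beam_log]),
#'   time-ordered and non-overlapping.
#' @return Integer vector of row indices into `beam_log` (`NA` when the
#'   timestamp falls in no delivery interval).
#' @export
associate_beam <- function(t_track, beam_log) {
  if (nrow(beam_log) == 0) return(rep(NA_integer_, length(t_track)))
  i <- findInterval(t_track, beam_log$t_start_ns)
  i[i == 0] <- NA_integer_
  ok <- !is.na(i) & t_track <= beam_log$t_end_ns[pmax(i, 1L)]
  i[!ok] <- NA_integer_
  i
}

#' Reconstruct fragmentation vertices by midpoint projection
#'
#' For each track, the pencil-beam line is the line through the nominal
#' logged spot position `(x_mm, y_mm, 0)` along the beam axis (+z). The
#' shortest connecting segment between the fragment track and that beam line
#' is computed; its midpoint is the reconstructed fragmentation vertex and
#' its length the miss distance. Using the nominal logged spot position
#' (rather than the unknown true primary trajectory) is part of what creates
#' the 3-5 mm projection uncertainty along the beam axis.
#'
#' @param tracks Track `data.frame` from [build_tracks].
#' @param beam_log Beam-record `data.frame`.
#' @param miss_cut Optional maximum miss distance, mm; vertices above it are
#'   dropped (off, `Inf`, by default).
#' @return A `data.frame` of vertices (`x`, `y`, `z`, `miss_mm`, `spot_id`,
#'   `t_ns`, `track_idx`). The attribute `"qc"` counts tracks excluded per
#'   reason (`no_beam`, `degenerate`, `miss_cut`).
#' @export
reconstruct_vertices <- function(tracks, beam_log, miss_cut = Inf) {
  n <- nrow(tracks)
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      miss_mm = numeric(), spot_id = integer(),
                      t_ns = numeric(), track_idx = integer())
  if (n == 0) {
    attr(empty, "qc") <- c(no_beam = 0L, degenerate = 0L, miss_cut = 0L)
    return(empty)
  }
  rec <- associate_beam(tracks$t_ns, beam_log)
  has_beam <- !is.na(rec)
  if (!any(has_beam)) {
    attr(empty, "qc") <- c(no_beam = sum(!has_beam), degenerate = 0L,
                           miss_cut = 0L)
    return(empty)
  }
  o1 <- cbind(tracks$fx, tracks$fy, tracks$fz)[has_beam, , drop = FALSE]
  u1 <- cbind(tracks$ux, tracks$uy, tracks$uz)[has_beam, , drop = FALSE]
  ri <- rec[has_beam]
  o2 <- cbind(beam_log$x_mm[ri], beam_log$y_mm[ri], rep(0, length(ri)))
  u2 <- matrix(rep(c(0, 0, 1), each = length(ri)), ncol = 3)
  ca <- .closest_approach_many(o1, u1, o2, u2)
  keep <- !ca$degenerate & ca$distance <= miss_cut
  out <- data.frame(x = ca$midpoint[keep, 1],
                    y = ca$midpoint[keep, 2],
                    z = ca$midpoint[keep, 3],
                    miss_mm = ca$distance[keep],
                    spot_id = beam_log$spot_id[ri[keep]],
                    t_ns = tracks$t_ns[has_beam][keep],
                    track_idx = which(has_beam)[keep])
  rownames(out) <- NULL
  attr(out, "qc") <- c(no_beam = sum(!has_beam),
                       degenerate = sum(ca$degenerate),
                       miss_cut = sum(!ca$degenerate & ca$distance > miss_cut))
  out
}

#' Residuals of reconstructed against true vertices
#'
#' Pairs reconstructed vertices with ground-truth vertices of the same
#' fragments and summarizes the per-axis residuals (reconstructed minus
#' true). The root-mean-square residual along the beam axis (z) is the
#' headline projection uncertainty of the method.
#'
#' @param reco Vertex `data.frame` from [reconstruct_vertices].
#' @param truth Ground-truth `data.frame` with columns `x`, `y`, `z` and a
#'   shared pairing key (see `by`).
#' @param by Name of the pairing key column present in both tables (default
#'   `"frag_id"`). Each key must occur at most once per table.
#' @return A list with `n_pairs`, per-axis `bias`, `rms` and residual
#'   `quantiles` (2.5/25/50/75/97.5%), plus the paired residual matrix
#'   `residuals` (columns x, y, z).
#' @export
vertex_residuals <- function(reco, truth, by = "frag_id") {
  stopifnot(by %in% names(reco), by %in% names(truth))
  i <- match(reco[[by]], truth[[by]])
  ok <- !is.na(i)
  if (!any(ok)) stop("no paired vertices between reco and truth")
  res <- cbind(x = reco$x[ok] - truth$x[i[ok]],
               y = reco$y[ok] - truth$y[i[ok]],
               z = reco$z[ok] - truth$z[i[ok]])
  qs <- apply(res, 2, stats::quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
  list(n_pairs = sum(ok),
       bias = colMeans(res),
       rms = sqrt(colMeans(res^2)),
       quantiles = qs,
       residuals = res)
}

#' Link reconstructed vertices to synthetic ground truth by timestamp
#'
#' Detected fragments are separated by microseconds at typical delivery
#' intensities while a fragment's hits share its emission time to within a
#' few nanoseconds of jitter, so nearest-time pairing within a small
#' tolerance identifies each track's fragment unambiguously. Adds the truth
#' `frag_id` to the vertex table for use with [vertex_residuals].
#'
#' @param vertices Vertex `data.frame` from [reconstruct_vertices].
#' @param truth Truth `data.frame` with columns `frag_id` and `t_ns`.
#' @param tol_ns Maximum |dt| for a valid link.
#' @return `vertices` with a `frag_id` column (`NA` where no truth row lies
#'   within `tol_ns`).
#' @export
link_truth <- function(vertices, truth, tol_ns = 40) {
  if (nrow(vertices) == 0) {
    vertices$frag_id <- integer()
    return(vertices)
  }
  ord <- order(truth$t_ns)
  tt <- truth$t_ns[ord]
  i <- findInterval(vertices$t_ns, tt)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(tt))
  d_lo <- abs(vertices$t_ns - tt[lo])
  d_hi <- abs(vertices$t_ns - tt[hi])
  best <- ifelse(d_hi < d_lo, hi, lo)
  d <- pmin(d_lo, d_hi)
  vertices$frag_id <- ifelse(d <= tol_ns, truth$frag_id[ord][best], NA_integer_)
  vertices
}
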