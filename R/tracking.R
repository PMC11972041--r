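#' Match front/back clusters into coincident pairs
#'
#' A fragment crossing the tracker leaves one cluster in each detection layer
#' within a few nanoseconds, so front and back clusters are paired by a
#' coincidence window on their timestamps (|dt| <= `window`, default 75 ns).
#' When several clusters compete inside a window, pairs are taken greedily by
#' smallest |dt|; ties are broken by the earlier front timestamp, then the
#' earlier back timestamp, which makes the matching deterministic.
#'
#' @param front,back Cluster `data.frame`s from [cluster_hits] (only the
#'   `t_ns` column is used for matching).
#' @param window Coincidence window, ns.
#' @return A list with `pairs` (a `data.frame` with `front_idx`, `back_idx`,
#'   row indices into the inputs, and `delta_t_ns = t_front - t_back`),
#'   `unmatched_front` and `unmatched_back` (integer index vectors).
#' @export
match_coincidences <- function(front, back, window = 75) {
  stopifnot(window > 0)
  nf <- nrow(front); nb <- nrow(back)
  m <- greedy_match_cpp(as.numeric(front$t_ns), as.numeric(back$t_ns), window)
  pairs <- data.frame(front_idx = m[, 1], back_idx = m[, 2],
                      delta_t_ns = front$t_ns[m[, 1]] - back$t_ns[m[, 2]])
  list(pairs = pairs,
       unmatched_front = setdiff(seq_len(nf), m[, 1]),
       unmatched_back = setdiff(seq_len(nb), m[, 2]))
}

#' Build fragment tracks from matched cluster pairs
#'
#' Maps the front and back cluster centroids of each coincident pair to room
#' coordinates and forms the track line through the two points, directed from
#' the front to the back layer (away from the phantom). Pairs whose mapped
#' points coincide are rejected as degenerate; tracks at more than
#' `flag_angle_deg` to the focus line are flagged as likely accidental
#' coincidences but kept.
#'
#' @param front,back Cluster `data.frame`s (as passed to
#'   [match_coincidences]; `front` must be the front layer).
#' @param matching Result of [match_coincidences].
#' @param geom A [tracker_geometry].
#' @param flag_angle_deg Polar-angle flag threshold to the focus line.
#' @return A `data.frame` of tracks: front/back room coordinates (`fx,fy,fz`,
#'   `bx,by,bz`), unit direction (`ux,uy,uz`), `t_ns` (front cluster
#'   timestamp), `delta_t_ns`, `angle_flag`, plus `front_idx`/`back_idx`
#'   provenance. Rejected pairs are recorded in the `"rejected"` attribute
#'   with a reason code.
#' @export
build_tracks <- function(front, back, matching, geom, flag_angle_deg = 45) {
  pairs <- matching$pairs
  n <- nrow(pairs)
  fp <- sensor_to_room(front$centroid_col[pairs$front_idx],
                       front$centroid_row[pairs$front_idx], "front", geom)
  bp <- sensor_to_room(back$centroid_col[pairs$back_idx],
                       back$centroid_row[pairs$back_idx], "back", geom)
  d <- bp - fp
  len <- sqrt(rowSums(d^2))
  ok <- len > 1e-9
  u <- d / len
  cosang <- as.vector(u %*% geom$focus_direction)
  tracks <- data.frame(
    fx = fp[, 1], fy = fp[, 2], fz = fp[, 3],
    bx = bp[, 1], by = bp[, 2], bz = bp[, 3],
    ux = u[, 1], uy = u[, 2], uz = u[, 3],
    t_ns = front$t_ns[pairs$front_idx],
    delta_t_ns = pairs$delta_t_ns,
    angle_flag = !ok | cosang < cos(flag_angle_deg * pi / 180),
    front_idx = pairs$front_idx,
    back_idx = pairs$back_idx
  )
  rejected <- data.frame(front_idx = pairs$front_idx[!ok],
                         back_idx = pairs$back_idx[!ok],
                         reason = rep("degenerate_identical_points", sum(!ok)))
  tracks <- tracks[ok, , drop = FALSE]
  rownames(tracks) <- NULL
  attr(tracks, "rejected") <- rejected
  tracks
}

#' Track line of one reconstructed track
#'
#' @param track One row of the track table from [build_tracks].
#' @return A [line3] through the two interaction points, directed front to
#'   back.
#' @export
track_line <- function(track) {
  line3(c(track$fx, track$fy, track$fz), c(track$ux, track$uy, track$uz))
}
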