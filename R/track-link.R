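#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour frame-to-frame assignment with gap
#' closing: a detection at frame `f` joins an existing track when the two
#' are mutual nearest neighbours within `max_displacement` px and the
#' track's last detection is at most `max_gap + 1` frames back. Each
#' detection is assigned to exactly one track; unmatched detections start
#' new tracks. Intended for non-crowded scenes (the synthetic generators
#' enforce 4-sigma spot spacing).
#'
#' @param detections Tibble with `frame` (0-based), `x`, `y` and any other
#'   per-detection columns (e.g. `amplitude`); master-channel detections.
#' @param max_displacement Maximum frame-to-frame displacement, px.
#' @param max_gap Maximum number of missed frames bridged within a track.
#' @return `detections` ordered by track and frame, with a `track_id`
#'   column.
#' @export
link_tracks <- function(detections, max_displacement = 3, max_gap = 2) {
  if (nrow(detections) == 0)
    return(mutate(detections, track_id = integer()))
  if (is.unsorted(detections$frame)) {
    ord <- order(detections$frame)
    detections <- detections[ord, ]
  }
  frames <- sort(unique(detections$frame))
  track_id <- integer(nrow(detections))
  # active track state
  tr_id <- integer(); tr_x <- numeric(); tr_y <- numeric()
  tr_last <- integer()
  next_id <- 1L
  for (f in frames) {
    rows <- which(detections$frame == f)
    dx <- detections$x[rows]; dy <- detections$y[rows]
    elig <- which(tr_last >= f - 1L - max_gap & tr_last < f)
    assigned <- rep(NA_integer_, length(rows))   # index into elig
    if (length(elig) && length(rows)) {
      D <- outer(tr_x[elig], dx, "-")^2 + outer(tr_y[elig], dy, "-")^2
      D[D > max_displacement^2] <- Inf
      repeat {
        if (all(!is.finite(D))) break
        # mutual nearest neighbours among remaining
        best_det <- apply(D, 1, which.min)   # per track
        best_tr <- apply(D, 2, which.min)    # per detection
        found <- FALSE
        for (ti in seq_along(elig)) {
          di <- best_det[ti]
          if (is.finite(D[ti, di]) && best_tr[di] == ti) {
            assigned[di] <- ti
            D[ti, ] <- Inf; D[, di] <- Inf
            found <- TRUE
          }
        }
        if (!found) break
      }
    }
    for (j in seq_along(rows)) {
      if (!is.na(assigned[j])) {
        ti <- elig[assigned[j]]
        track_id[rows[j]] <- tr_id[ti]
        tr_x[ti] <- dx[j]; tr_y[ti] <- dy[j]; tr_last[ti] <- f
      } else {
        track_id[rows[j]] <- next_id
        tr_id <- c(tr_id, next_id)
        tr_x <- c(tr_x, dx[j]); tr_y <- c(tr_y, dy[j])
        tr_last <- c(tr_last, f)
        next_id <- next_id + 1L
      }
    }
  }
  detections$track_id <- track_id
  arrange(detections, .data$track_id, .data$frame)
}
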