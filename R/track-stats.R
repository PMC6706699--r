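#' Classify tracks as persistent, bona fide, or transient
#'
#' A track is `persistent` when it spans the entire acquisition (first
#' frame 0 through frame `n_frames - 1`), regardless of amplitude.
#' Otherwise it is `bona_fide` when its maximum master amplitude reaches
#' `intensity_threshold` and it lasts at least `min_frames` frames
#' (intensity thresholding of trajectories separates bona fide CCPs from
#' transient coat assemblies), else `transient`. Persistent structures are
#' excluded from lifetime analyses and handled separately.
#'
#' @param tracks Long tibble with `track_id`, `frame`, `amplitude`
#'   (master channel rows only).
#' @param n_frames Acquisition length in frames.
#' @param frame_interval Frame interval, seconds.
#' @param intensity_threshold Master amplitude threshold (> 0).
#' @param min_frames Minimum track length (frames) for bona fide
#'   consideration.
#' @return Per-track tibble: `track_id`, `first`, `last`, `n_obs`,
#'   `lifetime_s`, `max_amplitude`, `category`.
#' @export
classify_tracks <- function(tracks, n_frames, frame_interval,
                            intensity_threshold, min_frames = 4L) {
  if (intensity_threshold <= 0) abort("intensity_threshold must be > 0")
  tracks |> group_by(.data$track_id) |>
    summarise(first = min(.data$frame), last = max(.data$frame),
              n_obs = dplyr::n(),
              max_amplitude = max(.data$amplitude), .groups = "drop") |>
    mutate(lifetime_s = (.data$last - .data$first + 1) * frame_interval,
           category = dplyr::case_when(
             .data$first == 0 & .data$last == n_frames - 1 ~ "persistent",
             .data$max_amplitude >= intensity_threshold &
               .data$n_obs >= min_frames ~ "bona_fide",
             TRUE ~ "transient"))
}

#' Per-track slave positivity
#'
#' A track is slave-positive when at least `min_significant_fraction` of
#' its frames carry a significant slave detection; used to subcategorize
#' CCPs into, e.g., NECAP-positive and NECAP-negative populations.
#'
#' @param tracks Long tibble with `track_id` and logical
#'   `slave_significant` per frame.
#' @param min_significant_fraction Fraction threshold in `[0, 1]`.
#' @return Tibble `track_id`, `significant_fraction`, `slave_positive`.
#' @export
slave_positivity <- function(tracks, min_significant_fraction = 0.3) {
  stopifnot("slave_significant" %in% names(tracks))
  tracks |> group_by(.data$track_id) |>
    summarise(significant_fraction = mean(.data$slave_significant),
              .groups = "drop") |>
    mutate(slave_positive =
             .data$significant_fraction >= min_significant_fraction)
}

#' Lifetime distribution statistics of bona fide CCPs
#'
#' Returns the mean lifetime, the 95th-percentile lifetime, and the
#' "average lifetime of the 95th percentile" interpreted as the mean of
#' the lifetimes at or above the 95th percentile (the top 5% of tracks).
#' Persistent tracks must be excluded upstream (use the `category` column
#' of [classify_tracks()]).
#'
#' @param lifetimes_s Lifetimes in seconds of >= 20 bona fide tracks.
#' @return One-row tibble: `n`, `mean_s`, `p95_s`, `p95_mean_s`.
#' @export
lifetime_stats <- function(lifetimes_s) {
  lifetimes_s <- lifetimes_s[is.finite(lifetimes_s)]
  if (length(lifetimes_s) < 20)
    abort("need at least 20 bona fide tracks for lifetime statistics")
  p95 <- quantile(lifetimes_s, 0.95, names = FALSE, type = 7)
  tibble(n = length(lifetimes_s), mean_s = mean(lifetimes_s), p95_s = p95,
         p95_mean_s = mean(lifetimes_s[lifetimes_s >= p95]))
}

#' Density of persistent structures
#'
#' @param n_persistent Count of persistent tracks in a cell.
#' @param cell_area_um2 Cell (mask) area in square micrometres (> 0).
#' @return Persistent structures per square micrometre.
#' @export
persistent_density <- function(n_persistent, cell_area_um2) {
  if (cell_area_um2 <= 0) abort("cell area must be > 0")
  n_persistent / cell_area_um2
}

#' Cohort-averaged intensity traces
#'
#' Groups bona fide tracks into lifetime cohorts and averages their
#' per-channel intensity traces on a common axis: each track's trace is
#' linearly resampled onto `n_points` equally spaced points spanning its
#' own lifetime, then the pointwise mean and standard error are computed
#' per cohort and channel. A single-track cohort has SE 0 by convention;
#' an empty cohort yields no rows.
#'
#' @param tracks Long tibble with `track_id`, `frame`, `channel`,
#'   `amplitude`.
#' @param classified Per-track tibble from [classify_tracks()] (only
#'   `bona_fide` tracks are used).
#' @param cohort_bounds List of increasing, non-overlapping lifetime
#'   intervals in seconds, e.g. `list(c(20, 40), c(40, 60))`; intervals
#'   are closed on the left, open on the right.
#' @param n_points Resampled trace length.
#' @return Tibble of class `ccp_cohorts`: `cohort` (label), `lifetime_lo`,
#'   `lifetime_hi`, `channel`, `point`, `rel_time` in `[0, 1]`, `mean`,
#'   `se`, `n_tracks`.
#' @export
cohort_traces <- function(tracks, classified,
                          cohort_bounds = list(c(20, 40), c(40, 60),
                                               c(60, 80), c(80, 120)),
                          n_points = 50L) {
  lo <- map_dbl(cohort_bounds, 1); hi <- map_dbl(cohort_bounds, 2)
  if (any(hi <= lo) || is.unsorted(lo) || any(head(hi, -1) > tail(lo, -1)))
    abort("cohort bounds must be increasing and non-overlapping")
  bona <- filter(classified, .data$category == "bona_fide")
  out <- list()
  for (ci in seq_along(cohort_bounds)) {
    ids <- bona$track_id[bona$lifetime_s >= lo[ci] & bona$lifetime_s < hi[ci]]
    if (length(ids) == 0) next
    sub <- tracks |> filter(.data$track_id %in% ids) |>
      arrange(.data$track_id, .data$channel, .data$frame)
    res <- sub |> group_by(.data$track_id, .data$channel) |>
      dplyr::reframe(point = seq_len(n_points),
                     value = if (dplyr::n() == 1)
                       rep(.data$amplitude, n_points)
                     else approx(seq(0, 1, length.out = dplyr::n()),
                                 .data$amplitude,
                                 xout = seq(0, 1, length.out = n_points))$y)
    sm <- res |> group_by(.data$channel, .data$point) |>
      summarise(mean = mean(.data$value),
                se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n())
                     else 0,
                n_tracks = dplyr::n(), .groups = "drop") |>
      mutate(cohort = sprintf("%g-%gs", lo[ci], hi[ci]),
             lifetime_lo = lo[ci], lifetime_hi = hi[ci],
             rel_time = (.data$point - 1) / (n_points - 1))
    out[[length(out) + 1L]] <- sm
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(channel = character(), point = integer(), mean = numeric(),
           se = numeric(), n_tracks = integer(), cohort = character(),
           lifetime_lo = numeric(), lifetime_hi = numeric(),
           rel_time = numeric())
  class(res) <- c("ccp_cohorts", class(res))
  res
}
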