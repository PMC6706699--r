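#' Simulate dual-channel CCP track tables with ground truth
#'
#' Bypasses image formation: draws a lifetime mixture of transient
#' assemblies and bona fide CCPs, gives each track a master intensity trace
#' (rise-plateau-fall for bona fide events, low flat for transients) and a
#' slave trace that is `slave_amplitude_ratio` times the master trace for
#' tracks drawn slave-positive (Bernoulli with the requested fraction) and
#' zero otherwise, then adds i.i.d. Gaussian noise of SD `noise_sd` to every
#' sample of both channels.
#'
#' @param n_tracks Number of tracks (>= 1).
#' @param lifetime_model As in [movie_spec()].
#' @param slave_positive_fraction Probability a track carries slave signal.
#' @param noise_sd Additive Gaussian noise SD (intensity units); must be
#'   non-negative.
#' @param frame_interval Sampling interval, seconds.
#' @param snr Peak master amplitude of bona fide tracks in units of
#'   `noise_sd` (peak amplitude = `snr * noise_sd` when `noise_sd > 0`,
#'   otherwise `snr`).
#' @param slave_amplitude_ratio Slave/master amplitude ratio for positives.
#' @param transient_amplitude_factor Transient peak relative to bona fide.
#' @param seed Integer seed.
#' @return List with `tracks`: a long tibble (`track_id`, `frame`, `time_s`,
#'   `master`, `slave`) and `truth`: one row per track (`track_id`,
#'   `category`, `n_obs`, `lifetime_s`, `slave_positive`,
#'   `peak_amplitude`).
#' @export
simulate_tracks <- function(n_tracks,
                            lifetime_model = list(transient_fraction = 0.4,
                                                  transient_mean_s = 6,
                                                  bona_fide_mean_s = 40),
                            slave_positive_fraction = 0.65,
                            noise_sd = 10, frame_interval = 2,
                            snr = 10, slave_amplitude_ratio = 0.8,
                            transient_amplitude_factor = 0.3,
                            seed = 1L) {
  if (n_tracks < 1) abort("n_tracks must be >= 1")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (slave_positive_fraction < 0 || slave_positive_fraction > 1)
    abort("slave_positive_fraction must be in [0, 1]")
  set.seed(seed)
  lt <- draw_lifetime_frames(n_tracks, lifetime_model, frame_interval)
  scale <- if (noise_sd > 0) noise_sd else 1
  peak <- snr * scale *
    ifelse(lt$category == "transient", transient_amplitude_factor, 1)
  positive <- runif(n_tracks) < slave_positive_fraction
  truth <- tibble(track_id = seq_len(n_tracks), category = lt$category,
                  n_obs = lt$n_obs,
                  lifetime_s = lt$n_obs * frame_interval,
                  slave_positive = positive, peak_amplitude = peak)
  tracks <- pmap(list(truth$track_id, truth$category, truth$n_obs,
                      truth$peak_amplitude, truth$slave_positive),
                 function(id, cat, n_obs, a, pos) {
                   m <- if (cat == "bona_fide") bona_fide_profile(n_obs, a)
                        else rep(a, n_obs)
                   s <- if (pos) slave_amplitude_ratio * m else rep(0, n_obs)
                   tibble(track_id = id, frame = seq_len(n_obs) - 1L,
                          time_s = (seq_len(n_obs) - 1L) * frame_interval,
                          master = m, slave = s)
                 }) |> list_rbind()
  if (noise_sd > 0) {
    tracks$master <- tracks$master + rnorm(nrow(tracks), 0, noise_sd)
    tracks$slave <- tracks$slave + rnorm(nrow(tracks), 0, noise_sd)
  }
  list(tracks = tracks, truth = truth)
}

#' Flag per-frame significant slave signal in a track table
#'
#' One-sided z-test of each slave sample against zero given the additive
#' noise SD: a frame is significant when its slave amplitude exceeds
#' `qnorm(1 - alpha) * noise_sd`. When `noise_sd` is `NULL` it is estimated
#' per track from the median absolute successive difference of the slave
#' trace (robust to the slowly varying recruitment profile).
#'
#' @param tracks Long track tibble with `track_id` and `slave` columns.
#' @param alpha One-sided significance level.
#' @param noise_sd Known noise SD, or `NULL` to estimate per track.
#' @return `tracks` with a logical `slave_significant` column.
#' @export
flag_slave_frames <- function(tracks, alpha = 0.05, noise_sd = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  z <- qnorm(1 - alpha)
  if (!is.null(noise_sd)) {
    stopifnot(noise_sd >= 0)
    tracks$slave_significant <- tracks$slave > z * noise_sd
    return(tracks)
  }
  tracks |>
    group_by(.data$track_id) |>
    mutate(slave_significant = .data$slave >
             z * pmax(mad(diff(.data$slave)) / sqrt(2), 1e-12)) |>
    ungroup()
}
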