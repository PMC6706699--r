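#' Simulate a multi-channel immunofluorescence still with ground truth
#'
#' Places `n_spots` master spots uniformly with minimum-spacing rejection
#' (4 sigma, as in [simulate_movie()]) and populates each secondary channel
#' at its co-occurrence probability. Secondary amplitudes are positively
#' correlated with the master amplitude through
#' `A_sec = ratio * (rho * A_master + (1 - rho) * mean(amplitude_range))`,
#' so `amplitude_correlation = 1` with noise disabled gives perfectly
#' correlated paired amplitudes.
#'
#' @param n_spots Number of master spots.
#' @param co_occurrence Named numeric vector of per-secondary-channel
#'   co-occurrence probabilities in `[0, 1]`, e.g. `c(p_ap2 = 0.7)`.
#' @param width,height Image size, pixels.
#' @param psf_sigma PSF sigma, pixels.
#' @param background_level,read_noise_sd,poisson_noise As [movie_spec()].
#' @param amplitude_range Master peak amplitude range (photons).
#' @param amplitude_correlation Correlation coefficient `rho` in `[0, 1]`.
#' @param secondary_amplitude_ratio Secondary/master amplitude ratio.
#' @param pixel_size_um Pixel size in micrometres.
#' @param seed Integer seed.
#' @return List of class `ccp_still`: `channels` (named list of matrices,
#'   `master` first), `pixel_size_um`, and `truth` with one row per spot
#'   (`spot_id`, `x`, `y`, `amplitude`, then one `<name>_positive` flag and
#'   `<name>_amplitude` per secondary channel).
#' @export
simulate_still <- function(n_spots, co_occurrence = c(secondary = 0.7),
                           width = 512, height = 512, psf_sigma = 1.1,
                           background_level = 100, read_noise_sd = 4,
                           amplitude_range = c(100, 150),
                           amplitude_correlation = 0.5,
                           secondary_amplitude_ratio = 0.8,
                           pixel_size_um = 0.0645,
                           poisson_noise = TRUE, seed = 1L) {
  if (any(co_occurrence < 0 | co_occurrence > 1))
    abort("co_occurrence probabilities must be in [0, 1]")
  if (is.null(names(co_occurrence)))
    names(co_occurrence) <- paste0("secondary", seq_along(co_occurrence))
  set.seed(seed)
  pos <- place_spots(n_spots, width, height, psf_sigma)
  amp <- runif(n_spots, amplitude_range[1], amplitude_range[2])
  truth <- tibble(spot_id = seq_len(n_spots), x = pos$x, y = pos$y,
                  amplitude = amp)
  rho <- amplitude_correlation
  for (ch in names(co_occurrence)) {
    positive <- runif(n_spots) < co_occurrence[[ch]]
    a_sec <- secondary_amplitude_ratio *
      (rho * amp + (1 - rho) * mean(amplitude_range))
    truth[[paste0(ch, "_positive")]] <- positive
    truth[[paste0(ch, "_amplitude")]] <- ifelse(positive, a_sec, 0)
  }

  render_still <- function(amplitudes) {
    img <- matrix(background_level, height, width)
    for (i in which(amplitudes > 0))
      img <- add_gaussian_patch(img, truth$x[i], truth$y[i], amplitudes[i],
                                psf_sigma)
    if (poisson_noise)
      img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
    if (read_noise_sd > 0)
      img <- img + rnorm(length(img), 0, read_noise_sd)
    pmax(img, 0)
  }
  channels <- c(list(master = render_still(truth$amplitude)),
                setNames(lapply(names(co_occurrence), function(ch)
                  render_still(truth[[paste0(ch, "_amplitude")]])),
                  names(co_occurrence)))
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 truth = truth),
            class = "ccp_still")
}

#' @export
print.ccp_still <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<ccp_still> %d x %d px, channels: %s, %d spots\n",
              d[2], d[1], paste(names(x$channels), collapse = ", "),
              nrow(x$truth)))
  invisible(x)
}
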