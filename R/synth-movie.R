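#' Specify a synthetic TIRF movie
#'
#' Builds the parameter set for [simulate_movie()]. Defaults emulate a
#' dual-colour live-cell TIRF acquisition of clathrin-coated pits: 0.5
#' frames/s over 10 minutes (300 frames at 2 s), a diffraction-limited PSF of
#' sigma 1.1 px for a 100x/1.49 NA objective with 6.45 um camera pixels, and
#' a CCP lifetime mixture of short-lived transient assemblies and longer
#' bona fide pits, plus a configurable number of persistent structures that
#' span the whole acquisition.
#'
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames.
#' @param frame_interval Frame interval in seconds.
#' @param psf_sigma Isotropic Gaussian PSF sigma in pixels.
#' @param background_level Constant background, photons.
#' @param read_noise_sd Additive Gaussian read noise SD, photons.
#' @param spot_amplitude_range Length-2 range of peak amplitudes (photons)
#'   for bona fide and persistent spots.
#' @param nucleation_rate Expected new (non-persistent) spots per frame.
#' @param lifetime_model List with `transient_fraction`, `transient_mean_s`,
#'   `bona_fide_mean_s` describing the two-population lifetime mixture.
#' @param transient_amplitude_factor Peak amplitude of transient assemblies
#'   relative to the drawn amplitude.
#' @param persistent_count Number of structures present in every frame.
#' @param slave_positive_fraction Probability that an event is rendered in
#'   the slave channel.
#' @param slave_amplitude_ratio Slave peak amplitude relative to master.
#' @param pixel_size_um Specimen-plane pixel size in micrometres.
#' @param poisson_noise Apply photon shot noise (Poisson on the noiseless
#'   image) before read noise.
#' @param seed Integer seed; identical specs and seeds give identical movies.
#' @return A list of class `movie_spec`.
#' @export
movie_spec <- function(width = 128, height = 128, n_frames = 300,
                       frame_interval = 2, psf_sigma = 1.1,
                       background_level = 100, read_noise_sd = 4,
                       spot_amplitude_range = c(100, 150),
                       nucleation_rate = 0.3,
                       lifetime_model = list(transient_fraction = 0.4,
                                             transient_mean_s = 6,
                                             bona_fide_mean_s = 40),
                       transient_amplitude_factor = 0.3,
                       persistent_count = 4,
                       slave_positive_fraction = 0.65,
                       slave_amplitude_ratio = 0.8,
                       pixel_size_um = 0.0645,
                       poisson_noise = TRUE, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_frames = as.integer(n_frames),
               frame_interval = frame_interval, psf_sigma = psf_sigma,
               background_level = background_level,
               read_noise_sd = read_noise_sd,
               spot_amplitude_range = spot_amplitude_range,
               nucleation_rate = nucleation_rate,
               lifetime_model = lifetime_model,
               transient_amplitude_factor = transient_amplitude_factor,
               persistent_count = as.integer(persistent_count),
               slave_positive_fraction = slave_positive_fraction,
               slave_amplitude_ratio = slave_amplitude_ratio,
               pixel_size_um = pixel_size_um,
               poisson_noise = isTRUE(poisson_noise), seed = as.integer(seed))
  validate_movie_spec(spec)
  structure(spec, class = "movie_spec")
}

validate_movie_spec <- function(spec) {
  stopifnot(spec$width > 0, spec$height > 0, spec$n_frames > 0)
  if (spec$frame_interval <= 0) abort("frame_interval must be > 0")
  if (spec$psf_sigma <= 0) abort("psf_sigma must be > 0")
  for (f in c("background_level", "read_noise_sd", "nucleation_rate",
              "persistent_count", "slave_amplitude_ratio"))
    if (spec[[f]] < 0) abort(paste(f, "must be non-negative"))
  p <- spec$slave_positive_fraction
  if (p < 0 || p > 1) abort("slave_positive_fraction must be in [0, 1]")
  lm <- spec$lifetime_model
  stopifnot(lm$transient_fraction >= 0, lm$transient_fraction <= 1,
            lm$transient_mean_s > 0, lm$bona_fide_mean_s > 0)
  invisible(spec)
}

# Rejection-sample spot centres with pairwise spacing >= 4 sigma. A scene
# too crowded to keep a mean nearest-neighbour spacing above 4 sigma is
# refused rather than silently rendered with overlapping spots.
place_spots <- function(n, width, height, psf_sigma, margin = NULL,
                        max_tries = 2000L) {
  if (n == 0L) return(tibble(x = numeric(), y = numeric()))
  min_sep <- 4 * psf_sigma
  margin <- margin %||% ceiling(5 * psf_sigma)
  if (width - 2 * margin <= min_sep || height - 2 * margin <= min_sep ||
      n > 0.5 * ((width - 2 * margin) / min_sep) *
              ((height - 2 * margin) / min_sep))
    abort(sprintf(paste("crowding: cannot place %d spots in %dx%d px at",
                        "spacing >= 4*psf_sigma = %.2f px"),
                  n, width, height, min_sep), class = "ccp_crowding_error")
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, margin, width - 1 - margin)
      y <- runif(1, margin, height - 1 - margin)
      if (i == 1L ||
          min((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2) >=
            min_sep^2) {
        xs[i] <- x; ys[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed)
      abort("crowding: rejection sampling failed to maintain 4*psf_sigma spacing",
            class = "ccp_crowding_error")
  }
  tibble(x = xs, y = ys)
}

# Piecewise-linear rise/plateau/fall amplitude profile for a bona fide CCP:
# linear rise over the first 30% of the lifetime, plateau, fall over the
# last 20%.
bona_fide_profile <- function(n_obs, peak) {
  if (n_obs < 4) return(rep(peak, n_obs))
  r <- max(1L, round(0.3 * n_obs))
  f <- max(1L, round(0.2 * n_obs))
  amp <- rep(peak, n_obs)
  amp[seq_len(r)] <- peak * seq_len(r) / r
  amp[n_obs - f + seq_len(f)] <- peak * rev(seq_len(f)) / f
  amp
}

draw_lifetime_frames <- function(n, lifetime_model, frame_interval) {
  transient <- runif(n) < lifetime_model$transient_fraction
  secs <- ifelse(transient,
                 rexp(n, 1 / lifetime_model$transient_mean_s),
                 rexp(n, 1 / lifetime_model$bona_fide_mean_s))
  frames <- pmax(ifelse(transient, 2L, 4L), round(secs / frame_interval))
  tibble(category = ifelse(transient, "transient", "bona_fide"),
         n_obs = as.integer(frames))
}

add_gaussian_patch <- function(img, x, y, amplitude, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(5 * sigma)
  cx <- round(x) + 1L; cy <- round(y) + 1L   # 1-based centre
  rows <- max(1L, cy - r):min(h, cy + r)
  cols <- max(1L, cx - r):min(w, cx + r)
  gy <- exp(-((rows - 1 - y)^2) / (2 * sigma^2))
  gx <- exp(-((cols - 1 - x)^2) / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + amplitude * outer(gy, gx)
  img
}

#' Simulate a two-channel CCP movie with ground truth
#'
#' Renders each spot as an isotropic 2D Gaussian of width `psf_sigma` on a
#' constant background, applies photon shot noise (Poisson on the noiseless
#' image) followed by additive Gaussian read noise, and returns per-channel
#' frame stacks together with a complete ground-truth event ledger.
#' Bona fide events follow a rise-plateau-fall amplitude profile, transient
#' events a low flat profile, and persistent structures are rendered at
#' constant amplitude in every frame. The slave channel renders only events
#' drawn slave-positive, at `slave_amplitude_ratio` times the master
#' amplitude. Positions are static and kept at pairwise spacing of at least
#' 4 sigma (a crowding error is raised otherwise).
#'
#' @param spec A [movie_spec()].
#' @return A list of class `ccp_movie` with elements `channels` (named list
#'   of height x width x n_frames arrays, here `master` and `slave`),
#'   `frame_interval`, `pixel_size_um`, `spec`, and `truth`: a tibble with
#'   one row per event (`event_id`, `x`, `y` in 0-based pixel-centre
#'   coordinates, `birth`, `death` 0-based frames, `category`,
#'   `slave_positive`, `peak_amplitude`, and the list-column `trace` of
#'   per-frame master amplitudes).
#' @export
simulate_movie <- function(spec) {
  validate_movie_spec(spec)
  set.seed(spec$seed)
  nT <- spec$n_frames
  lt <- draw_lifetime_frames(
    n = rpois(1, spec$nucleation_rate * max(nT - 1, 0)),
    lifetime_model = spec$lifetime_model,
    frame_interval = spec$frame_interval)
  n_dyn <- nrow(lt)
  births <- if (n_dyn) sample.int(max(nT - 1, 1), n_dyn, replace = TRUE) else integer()
  events <- tibble(
    category = c(rep("persistent", spec$persistent_count), lt$category),
    birth = as.integer(c(rep(0L, spec$persistent_count), births)),
    n_obs = as.integer(c(rep(nT, spec$persistent_count), lt$n_obs)))
  events$death <- pmin(events$birth + events$n_obs - 1L, nT - 1L)
  events$n_obs <- events$death - events$birth + 1L
  n_ev <- nrow(events)
  pos <- place_spots(n_ev, spec$width, spec$height, spec$psf_sigma)
  peak <- runif(n_ev, spec$spot_amplitude_range[1], spec$spot_amplitude_range[2])
  peak[events$category == "transient"] <-
    peak[events$category == "transient"] * spec$transient_amplitude_factor
  traces <- pmap(list(events$category, events$n_obs, peak),
                 function(cat, n_obs, a) {
                   if (cat == "bona_fide") bona_fide_profile(n_obs, a)
                   else rep(a, n_obs)
                 })
  truth <- tibble(event_id = seq_len(n_ev), x = pos$x, y = pos$y,
                  birth = events$birth, death = events$death,
                  category = events$category,
                  slave_positive = runif(n_ev) < spec$slave_positive_fraction,
                  peak_amplitude = peak, trace = traces)

  render_channel <- function(ratio, keep) {
    arr <- array(0, dim = c(spec$height, spec$width, nT))
    for (f in seq_len(nT) - 1L) {
      img <- matrix(spec$background_level, spec$height, spec$width)
      live <- which(keep & truth$birth <= f & truth$death >= f)
      for (i in live) {
        a <- ratio * truth$trace[[i]][f - truth$birth[i] + 1L]
        img <- add_gaussian_patch(img, truth$x[i], truth$y[i], a, spec$psf_sigma)
      }
      if (spec$poisson_noise)
        img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
      if (spec$read_noise_sd > 0)
        img <- img + rnorm(length(img), 0, spec$read_noise_sd)
      arr[, , f + 1L] <- pmax(img, 0)
    }
    arr
  }
  channels <- list(
    master = render_channel(1, rep(TRUE, n_ev)),
    slave  = render_channel(spec$slave_amplitude_ratio, truth$slave_positive))
  structure(list(channels = channels, frame_interval = spec$frame_interval,
                 pixel_size_um = spec$pixel_size_um, spec = spec,
                 truth = truth),
            class = "ccp_movie")
}

#' @export
print.ccp_movie <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<ccp_movie> %d x %d px, %d frames @ %gs, channels: %s, %d events\n",
              d[2], d[1], d[3], x$frame_interval,
              paste(names(x$channels), collapse = ", "), nrow(x$truth)))
  invisible(x)
}

#' Cell area covered by a movie or still, in square micrometres
#' @param x A `ccp_movie` or `ccp_still`.
#' @return Area in um^2 (full field of view).
#' @export
field_area_um2 <- function(x) {
  d <- dim(if (is.matrix(x$channels[[1]])) x$channels[[1]] else
           x$channels[[1]][, , 1, drop = FALSE])
  d[1] * d[2] * x$pixel_size_um^2
}
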