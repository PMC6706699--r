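#' Detection configuration
#'
#' Parameters for spot detection and master/slave quantification.
#' Coordinates throughout are 0-based, pixel-centre, with `x` the column
#' and `y` the row.
#'
#' @param psf_sigma Expected PSF sigma, pixels. The Gaussian fit holds
#'   sigma fixed at this value unless `free_sigma = TRUE`.
#' @param alpha One-sided significance level of the amplitude test; also
#'   sets the noise multiple `k = qnorm(1 - alpha)` the amplitude must
#'   exceed.
#' @param window_radius Half-width of the square fit window, pixels; must
#'   be at least `2 * psf_sigma`.
#' @param slave_search_radius Maximum displacement of a slave-channel fit
#'   position from its master position, pixels.
#' @param free_sigma Also refine sigma in the fit.
#' @param candidate_mad_factor Permissive candidate threshold: local maxima
#'   of the band-passed frame must exceed this multiple of the band-passed
#'   frame's MAD.
#' @return List of class `detection_config`.
#' @export
detection_config <- function(psf_sigma = 1.1, alpha = 0.05,
                             window_radius = 4, slave_search_radius = 2,
                             free_sigma = FALSE, candidate_mad_factor = 3) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (window_radius < 2 * psf_sigma)
    abort("window_radius must be >= 2 * psf_sigma")
  structure(list(psf_sigma = psf_sigma, alpha = alpha,
                 window_radius = as.integer(window_radius),
                 slave_search_radius = slave_search_radius,
                 free_sigma = isTRUE(free_sigma),
                 candidate_mad_factor = candidate_mad_factor),
            class = "detection_config")
}

#' Candidate spot positions from a difference-of-Gaussians band-pass
#'
#' Band-passes the frame with a difference of Gaussians matched to the PSF
#' (sigma and 1.6 sigma), then returns integer pixel positions that are
#' strict 8-neighbour local maxima above a low permissive threshold
#' (`candidate_mad_factor` times the MAD of the band-passed frame).
#'
#' @param frame Numeric matrix (rows = y, columns = x).
#' @param config A [detection_config()].
#' @return Tibble with integer `x`, `y` (0-based) and the band-pass
#'   `response`; empty when no candidate exceeds the threshold.
#' @export
find_candidates <- function(frame, config = detection_config()) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  s <- config$psf_sigma
  dog <- EBImage::gblur(frame, sigma = s, boundary = "replicate") -
    EBImage::gblur(frame, sigma = 1.6 * s, boundary = "replicate")
  thr <- config$candidate_mad_factor * mad(dog)
  h <- nrow(dog); w <- ncol(dog)
  if (h < 3 || w < 3) return(tibble(x = integer(), y = integer(),
                                    response = numeric()))
  core <- dog[2:(h - 1), 2:(w - 1)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (core > dog[2:(h - 1) + dy, 2:(w - 1) + dx])
  }
  idx <- which(is_max, arr.ind = TRUE)
  tibble(x = as.integer(idx[, 2] + 1L - 1L),   # core col j -> frame col j+1
         y = as.integer(idx[, 1] + 1L - 1L),
         response = core[is_max]) |>
    arrange(dplyr::desc(.data$response))
}

# Damped Gauss-Newton least squares of A*exp(-r^2/(2 sigma^2)) + c over a
# square window. Position is initialized at `init` and, when `bound` is
# given, clamped to a box of that half-width around it (slave fits); it is
# always kept inside the window. Returns parameter estimates, the standard
# error of A from the inverse Gauss-Newton Hessian, and a one-sided t-test
# of A > 0 against the residual noise with (npix - nparam) df.
fit_gaussian_window <- function(win, x_off, y_off, init_x, init_y, sigma,
                                free_sigma = FALSE, bound = NULL,
                                k_noise = qnorm(0.95), max_iter = 100L) {
  h <- nrow(win); w <- ncol(win)
  X <- matrix(rep(x_off + seq_len(w) - 1, each = h), h, w)
  Y <- matrix(rep(y_off + seq_len(h) - 1, times = w), h, w)
  xv <- as.numeric(X); yv <- as.numeric(Y); zv <- as.numeric(win)
  npar <- if (free_sigma) 5L else 4L
  n <- length(zv)
  lo_x <- x_off; hi_x <- x_off + w - 1
  lo_y <- y_off; hi_y <- y_off + h - 1
  if (!is.null(bound)) {
    lo_x <- max(lo_x, init_x - bound); hi_x <- min(hi_x, init_x + bound)
    lo_y <- max(lo_y, init_y - bound); hi_y <- min(hi_y, init_y + bound)
  }
  g_of <- function(x0, y0, s)
    exp(-((xv - x0)^2 + (yv - y0)^2) / (2 * s^2))
  lin_solve <- function(g) {
    sg <- sum(g); sgg <- sum(g * g)
    det <- n * sgg - sg^2
    if (det <= 0) return(c(A = 0, c = mean(zv)))
    A <- (n * sum(g * zv) - sg * sum(zv)) / det
    c0 <- (sum(zv) - A * sg) / n
    c(A = A, c = c0)
  }
  x0 <- init_x; y0 <- init_y; s <- sigma
  g <- g_of(x0, y0, s); ac <- lin_solve(g)
  A <- ac[["A"]]; c0 <- ac[["c"]]
  rss <- sum((zv - A * g - c0)^2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r2x <- (xv - x0); r2y <- (yv - y0)
    J <- cbind(g, 1, A * g * r2x / s^2, A * g * r2y / s^2)
    if (free_sigma) J <- cbind(J, A * g * (r2x^2 + r2y^2) / s^3)
    res <- zv - A * g - c0
    step <- tryCatch(solve(crossprod(J), crossprod(J, res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (half in 1:8) {
      A_n <- A + lambda * step[1]; c_n <- c0 + lambda * step[2]
      x_n <- min(max(x0 + lambda * step[3], lo_x), hi_x)
      y_n <- min(max(y0 + lambda * step[4], lo_y), hi_y)
      s_n <- if (free_sigma) max(s + lambda * step[5], 0.3) else s
      g_n <- g_of(x_n, y_n, s_n)
      rss_n <- sum((zv - A_n * g_n - c_n)^2)
      if (rss_n <= rss) {
        delta <- max(abs(c(A_n - A, c_n - c0, x_n - x0, y_n - y0, s_n - s)))
        A <- A_n; c0 <- c_n; x0 <- x_n; y0 <- y_n; s <- s_n
        g <- g_n; rss <- rss_n
        improved <- TRUE
        if (delta < 1e-8) converged <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved || converged) { converged <- converged || !improved; break }
  }
  # amplitude standard error from the Gauss-Newton normal equations
  r2x <- (xv - x0); r2y <- (yv - y0)
  J <- cbind(g, 1, A * g * r2x / s^2, A * g * r2y / s^2)
  if (free_sigma) J <- cbind(J, A * g * (r2x^2 + r2y^2) / s^3)
  df_resid <- n - npar
  sigma2 <- rss / df_resid
  cov_A <- tryCatch(solve(crossprod(J))[1, 1] * sigma2,
                    error = function(e) NA_real_)
  se_A <- sqrt(max(cov_A, 0))
  # one-sided test of A > k * residual noise SD (k = qnorm(1 - alpha)):
  # statistic is the amplitude margin over its propagated standard error,
  # referred to a t distribution with (npix - nparam) df
  t_stat <- if (is.finite(se_A) && se_A > 0)
    (A - k_noise * sqrt(sigma2)) / se_A else NA_real_
  p <- if (is.finite(t_stat)) pt(t_stat, df_resid, lower.tail = FALSE)
       else NA_real_
  list(x = x0, y = y0, A = A, c = c0, sigma = s,
       residual_noise_sd = sqrt(sigma2), se_A = se_A, p_value = p,
       converged = converged, valid = is.finite(p))
}

#' Fit a 2D Gaussian spot at a seed position
#'
#' Least-squares fit of `A exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2)) + c`
#' over a `(2 window_radius + 1)^2` window centred on the seed, sigma fixed
#' to `config$psf_sigma` (refined too when `config$free_sigma`). The fitted
#' amplitude is tested one-sided against the residual background noise
#' estimated at the location: the null is `A = k * residual_noise_sd` with
#' `k = qnorm(1 - alpha)`, the statistic is the amplitude margin over its
#' propagated standard error, referred to a t distribution with (window
#' pixels - free parameters) degrees of freedom; `significant` is
#' `p_value < alpha`.
#'
#' @param frame Numeric matrix.
#' @param seed_position Length-2 vector `c(x, y)`, 0-based integer pixel.
#' @param config A [detection_config()].
#' @return One-row tibble: `x`, `y`, `sigma`, `amplitude`, `background`,
#'   `residual_noise_sd`, `se_amplitude`, `p_value`, `significant`,
#'   `valid`.
#' @export
fit_spot <- function(frame, seed_position, config = detection_config()) {
  r <- config$window_radius
  cx <- round(seed_position[1]); cy <- round(seed_position[2])
  h <- nrow(frame); w <- ncol(frame)
  if (cx - r < 0 || cx + r > w - 1 || cy - r < 0 || cy + r > h - 1)
    abort("seed window extends beyond the frame")
  win <- frame[(cy - r):(cy + r) + 1L, (cx - r):(cx + r) + 1L]
  f <- fit_gaussian_window(win, x_off = cx - r, y_off = cy - r,
                           init_x = cx, init_y = cy,
                           sigma = config$psf_sigma,
                           free_sigma = config$free_sigma,
                           k_noise = qnorm(1 - config$alpha))
  tibble(x = f$x, y = f$y, sigma = f$sigma, amplitude = f$A,
         background = f$c, residual_noise_sd = f$residual_noise_sd,
         se_amplitude = f$se_A, p_value = f$p_value,
         significant = isTRUE(f$p_value < config$alpha),
         valid = f$valid)
}

#' Detect and fit all spots in a frame
#'
#' Runs [find_candidates()], fits each candidate whose full window lies
#' inside the frame with [fit_spot()], merges duplicate fits within 1 px
#' keeping the higher amplitude, and returns significant detections (all
#' fits, including insignificant ones, with `all = TRUE`).
#'
#' @param frame Numeric matrix.
#' @param config A [detection_config()].
#' @param all Return insignificant fits too (flagged by `significant`).
#' @return Detection tibble as in [fit_spot()] plus `candidate_x`,
#'   `candidate_y`; attribute `frame_dim` records the frame geometry.
#' @export
detect_frame <- function(frame, config = detection_config(), all = FALSE) {
  cand <- find_candidates(frame, config)
  r <- config$window_radius
  h <- nrow(frame); w <- ncol(frame)
  cand <- filter(cand, .data$x >= r, .data$x <= w - 1 - r,
                 .data$y >= r, .data$y <= h - 1 - r)
  k_noise <- qnorm(1 - config$alpha)
  nc <- nrow(cand)
  M <- matrix(NA_real_, nc, 9)
  for (i in seq_len(nc)) {
    cx <- cand$x[i]; cy <- cand$y[i]
    win <- frame[(cy - r):(cy + r) + 1L, (cx - r):(cx + r) + 1L]
    f <- fit_gaussian_window(win, x_off = cx - r, y_off = cy - r,
                             init_x = cx, init_y = cy,
                             sigma = config$psf_sigma,
                             free_sigma = config$free_sigma,
                             k_noise = k_noise)
    M[i, ] <- c(f$x, f$y, f$sigma, f$A, f$c, f$residual_noise_sd, f$se_A,
                f$p_value, as.numeric(f$valid))
  }
  dets <- tibble(x = M[, 1], y = M[, 2], sigma = M[, 3], amplitude = M[, 4],
                 background = M[, 5], residual_noise_sd = M[, 6],
                 se_amplitude = M[, 7], p_value = M[, 8],
                 significant = !is.na(M[, 8]) & M[, 8] < config$alpha,
                 valid = M[, 9] == 1,
                 candidate_x = cand$x, candidate_y = cand$y)
  if (nrow(dets) > 0) {
    dets <- arrange(dets, dplyr::desc(.data$amplitude))
    keep <- rep(TRUE, nrow(dets))
    for (i in seq_len(nrow(dets))[-1]) {
      prev <- which(keep[seq_len(i - 1)])
      if (any((dets$x[prev] - dets$x[i])^2 +
              (dets$y[prev] - dets$y[i])^2 < 1))
        keep[i] <- FALSE
    }
    dets <- dets[keep, ]
  }
  if (!all) dets <- filter(dets, .data$significant)
  attr(dets, "frame_dim") <- dim(frame)
  dets
}

#' Measure slave-channel signal at master detection positions
#'
#' For every master detection, fits a 2D Gaussian in the slave channel with
#' the fit position constrained to lie within `slave_search_radius` of the
#' master position, and tests the amplitude as in [fit_spot()]. The output
#' is paired 1:1 and order-preserving with the master detections: a row is
#' produced for every master, including insignificant (or edge-invalid)
#' slave measurements.
#'
#' @param master_detections Detection tibble from [detect_frame()].
#' @param slave_frame Slave-channel matrix, same geometry as the master
#'   frame.
#' @param config A [detection_config()].
#' @return Tibble with one row per master: slave `x`, `y`, `sigma`,
#'   `amplitude`, `background`, `residual_noise_sd`, `se_amplitude`,
#'   `p_value`, `significant`, `valid`, plus `master_x`, `master_y`,
#'   `offset_px`.
#' @export
measure_slave <- function(master_detections, slave_frame,
                          config = detection_config()) {
  fd <- attr(master_detections, "frame_dim")
  if (!is.null(fd) && !identical(fd, dim(slave_frame)))
    abort("slave frame geometry does not match the master frame")
  r <- config$window_radius
  h <- nrow(slave_frame); w <- ncol(slave_frame)
  k_noise <- qnorm(1 - config$alpha)
  nm <- nrow(master_detections)
  M <- matrix(NA_real_, nm, 9)
  for (i in seq_len(nm)) {
    mx <- master_detections$x[i]; my <- master_detections$y[i]
    cx <- round(mx); cy <- round(my)
    if (cx - r < 0 || cx + r > w - 1 || cy - r < 0 || cy + r > h - 1) next
    win <- slave_frame[(cy - r):(cy + r) + 1L, (cx - r):(cx + r) + 1L]
    f <- fit_gaussian_window(win, x_off = cx - r, y_off = cy - r,
                             init_x = mx, init_y = my,
                             sigma = config$psf_sigma,
                             free_sigma = config$free_sigma,
                             bound = config$slave_search_radius,
                             k_noise = k_noise)
    M[i, ] <- c(f$x, f$y, f$sigma, f$A, f$c, f$residual_noise_sd, f$se_A,
                f$p_value, as.numeric(f$valid))
  }
  out <- tibble(x = M[, 1], y = M[, 2], sigma = M[, 3], amplitude = M[, 4],
                background = M[, 5], residual_noise_sd = M[, 6],
                se_amplitude = M[, 7], p_value = M[, 8],
                significant = !is.na(M[, 8]) & M[, 8] < config$alpha,
                valid = !is.na(M[, 9]) & M[, 9] == 1,
                master_x = master_detections$x,
                master_y = master_detections$y,
                offset_px = sqrt((M[, 1] - master_detections$x)^2 +
                                 (M[, 2] - master_detections$y)^2))
  attr(out, "frame_dim") <- dim(slave_frame)
  out
}

#' Detect a whole movie, master channel with dependent slaves
#'
#' Applies [detect_frame()] to every master frame and [measure_slave()] to
#' every slave channel at the master positions.
#'
#' @param movie A `ccp_movie` (or list with `channels` of 3D arrays).
#' @param config A [detection_config()].
#' @param master Name of the master channel (default first).
#' @param channels Channels to process (subset to just the master to skip
#'   slave quantification).
#' @return Long tibble of detections with `frame` (0-based), `channel`,
#'   and the [fit_spot()] columns; slave rows carry `master_x`, `master_y`.
#' @export
detect_movie <- function(movie, config = detection_config(),
                         master = names(movie$channels)[1],
                         channels = names(movie$channels)) {
  slaves <- setdiff(intersect(names(movie$channels), channels), master)
  nT <- dim(movie$channels[[master]])[3]
  out <- vector("list", nT)
  for (f in seq_len(nT)) {
    md <- detect_frame(movie$channels[[master]][, , f], config)
    if (nrow(md) == 0) next
    md$frame <- f - 1L; md$channel <- master
    parts <- list(md)
    for (sl in slaves) {
      sd_ <- measure_slave(md, movie$channels[[sl]][, , f], config)
      sd_$frame <- f - 1L; sd_$channel <- sl
      parts[[length(parts) + 1L]] <- sd_
    }
    out[[f]] <- bind_rows(parts)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0)
    res <- tibble(x = numeric(), y = numeric(), amplitude = numeric(),
                  significant = logical(), frame = integer(),
                  channel = character())
  res
}
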