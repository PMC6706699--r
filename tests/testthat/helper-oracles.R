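# Independent oracles and fixture builders used across the suite.

# Render a frame of 2D Gaussian spots by direct per-pixel evaluation
# (independent of the package's patch-based renderer).
oracle_frame <- function(width, height, spots, background = 0, sigma = 1.1) {
  img <- matrix(background, height, width)
  for (r in seq_len(height)) for (c in seq_len(width)) {
    x <- c - 1; y <- r - 1
    img[r, c] <- img[r, c] + sum(spots$A *
      exp(-((x - spots$x)^2 + (y - spots$y)^2) / (2 * sigma^2)))
  }
  img
}

# Greedy one-to-one matching of detections to ground-truth spots within a
# radius; returns the number of matched truth spots.
match_count <- function(dets, truth, radius = 2) {
  if (nrow(dets) == 0 || nrow(truth) == 0) return(0L)
  used <- rep(FALSE, nrow(dets))
  n <- 0L
  for (i in seq_len(nrow(truth))) {
    d2 <- (dets$x - truth$x[i])^2 + (dets$y - truth$y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= radius^2) { used[j] <- TRUE; n <- n + 1L }
  }
  n
}

# Textbook Welch t-test from first principles.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# ITC heats by direct numerical mass-balance integration per injection:
# same mixing/displacement convention as the package model, but the
# equilibrium is solved numerically for the free ligand with uniroot
# instead of the closed-form quadratic.
itc_oracle_heats <- function(K_D, n, dH, cell_conc, syringe_conc,
                             cell_volume_ul = 170,
                             injection_volumes_ul = rep(2.43, 20)) {
  V0 <- cell_volume_ul * 1e-6
  M <- cell_conc; X <- 0; B_prev <- 0
  q <- numeric(length(injection_volumes_ul))
  for (i in seq_along(injection_volumes_ul)) {
    dv <- injection_volumes_ul[i] * 1e-6
    d <- V0 / (V0 + dv)
    M <- M * d
    X <- (X * V0 + syringe_conc * dv) / (V0 + dv)
    S <- n * M
    f <- function(Lf) Lf + S * Lf / (K_D + Lf) - X
    Lf <- if (X == 0) 0 else uniroot(f, c(0, X), tol = 1e-15)$root
    B <- X - Lf
    q[i] <- dH * 1e9 * V0 * (B - B_prev * d)
    B_prev <- B
  }
  q
}

# 99% binomial CI half-width around a planted proportion.
binom_ci_halfwidth <- function(p, n, z = qnorm(0.995)) z * sqrt(p * (1 - p) / n)
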