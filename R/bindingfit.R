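new_binding_fit <- function(model, estimates, se, rss, n, converged,
                            data, fitted, flags = character()) {
  structure(list(model = model, estimates = estimates, se = se, rss = rss,
                 n = n, converged = converged, data = data, fitted = fitted,
                 residuals = NULL, flags = flags),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit: %s> %s\n", x$model,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a binding fit
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = unname(x$estimates),
         std.error = unname(x$se[names(x$estimates)]))
}

#' One-row summary of a binding fit
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `rss`, `sigma`, `n`, `converged`, `flags`.
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(model = x$model, rss = x$rss,
         sigma = sqrt(x$rss / max(x$n - length(x$estimates), 1)),
         n = x$n, converged = x$converged,
         flags = paste(x$flags, collapse = ";"))
}

# Wrap minpack.lm::nlsLM, returning estimates/SEs/RSS without erroring on
# failed convergence.
nls_lm_fit <- function(formula, data, start, lower = NULL, upper = NULL) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  se <- if (is.null(sm)) setNames(rep(NA_real_, length(coef(fit))),
                                  names(coef(fit)))
        else sm$coefficients[, "Std. Error"]
  list(coef = coef(fit), se = se, rss = sum(residuals(fit)^2),
       fitted = as.numeric(fitted(fit)))
}

# Delta-method SE for K = 10^lk given SE of lk.
log10_se <- function(K, se_lk) abs(K * log(10)) * se_lk

#' Fit the single-site anisotropy model
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `F = F_f + (F_b - F_f) [L] / (K_d + [L])` with `K_d` log-parameterized to
#' enforce positivity. If the titration does not approach saturation
#' (fitted `K_d` beyond the highest ligand concentration) the fit is
#' flagged and `converged` is `FALSE`.
#'
#' @param data Tibble with `ligand_uM` (or any strictly increasing,
#'   non-negative concentration column named first) and `anisotropy`.
#' @return A [`binding_fit`][tidy.binding_fit] with estimates `F_f`, `F_b`,
#'   `K_d` (in the unit of the concentration column).
#' @export
fit_anisotropy <- function(data) {
  xcol <- names(data)[1]; ycol <- names(data)[2]
  L <- data[[xcol]]; F_obs <- data[[ycol]]
  if (length(L) < 5) abort("need at least 5 titration points")
  if (any(L < 0) || is.unsorted(L, strictly = TRUE))
    abort("concentrations must be non-negative and strictly increasing")
  df <- tibble(L = L, F_obs = F_obs)
  start <- list(F_f = min(F_obs), F_b = max(F_obs),
                lk = log10(max(median(L[L > 0]), 1e-6)))
  res <- nls_lm_fit(F_obs ~ F_f + (F_b - F_f) * L / (10^lk + L), df, start)
  if (is.null(res))
    return(new_binding_fit("anisotropy", c(F_f = NA, F_b = NA, K_d = NA),
                           c(F_f = NA, F_b = NA, K_d = NA), NA_real_,
                           nrow(df), FALSE, data, NULL, "no_convergence"))
  K <- 10^res$coef[["lk"]]
  est <- c(F_f = res$coef[["F_f"]], F_b = res$coef[["F_b"]], K_d = K)
  se <- c(F_f = res$se[["F_f"]], F_b = res$se[["F_b"]],
          K_d = log10_se(K, res$se[["lk"]]))
  flags <- character()
  converged <- TRUE
  if (K > max(L)) {                      # no saturation reached in design
    flags <- "no_saturation"
    converged <- FALSE
  }
  new_binding_fit("anisotropy", est, se, res$rss, nrow(df), converged,
                  data, res$fitted, flags)
}

#' Fit a biexponential SPR dissociation phase
#'
#' `R(t) = A_fast exp(-k_fast t) + A_slow exp(-k_slow t)` by
#' Levenberg-Marquardt with five deterministic multi-starts spanning
#' log-spaced rate ratios; the returned components are always ordered
#' `k_fast > k_slow`. Near-degenerate rates (`k_fast / k_slow < 1.5`) are
#' flagged `rate_degeneracy`.
#'
#' @param data Tibble with `time_s` and `response` (dissociation phase only,
#'   time increasing from the start of dissociation).
#' @return A `binding_fit` with `A_fast`, `k_fast`, `A_slow`, `k_slow`.
#' @export
fit_dissociation <- function(data) {
  t <- data[[1]]; R <- data[[2]]
  if (length(t) < 20) abort("need at least 20 dissociation points")
  if (is.unsorted(t)) abort("time must be increasing within the phase")
  df <- tibble(t = t, R = R)
  span <- max(t) - min(t)
  k0 <- log(2) / (span / 4 + 1e-9)
  ratios <- 10^seq(0.25, 2.25, length.out = 5)   # k_fast / k_slow starts
  best <- NULL
  for (r in ratios) {
    start <- list(A1 = sum(range(R)) / 2, A2 = sum(range(R)) / 2,
                  lk1 = log10(k0 * sqrt(r)), lk2 = log10(k0 / sqrt(r)))
    res <- nls_lm_fit(R ~ A1 * exp(-10^lk1 * t) + A2 * exp(-10^lk2 * t),
                      df, start)
    if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
  }
  if (is.null(best))
    return(new_binding_fit("spr_dissociation",
                           setNames(rep(NA_real_, 4),
                                    c("A_fast", "k_fast", "A_slow", "k_slow")),
                           setNames(rep(NA_real_, 4),
                                    c("A_fast", "k_fast", "A_slow", "k_slow")),
                           NA_real_, nrow(df), FALSE, data, NULL,
                           "no_convergence"))
  k1 <- 10^best$coef[["lk1"]]; k2 <- 10^best$coef[["lk2"]]
  ord <- if (k1 >= k2) c("1", "2") else c("2", "1")
  ks <- c(k1, k2)[as.integer(ord)]
  As <- c(best$coef[["A1"]], best$coef[["A2"]])[as.integer(ord)]
  kse <- c(log10_se(k1, best$se[["lk1"]]),
           log10_se(k2, best$se[["lk2"]]))[as.integer(ord)]
  Ase <- c(best$se[["A1"]], best$se[["A2"]])[as.integer(ord)]
  est <- c(A_fast = As[1], k_fast = ks[1], A_slow = As[2], k_slow = ks[2])
  se <- c(A_fast = Ase[1], k_fast = kse[1], A_slow = Ase[2], k_slow = kse[2])
  flags <- if (ks[2] > 0 && ks[1] / ks[2] < 1.5) "rate_degeneracy"
           else character()
  new_binding_fit("spr_dissociation", est, se, best$rss, nrow(df), TRUE,
                  data, best$fitted, flags)
}

#' Fit a 1:1 amplitude isotherm
#'
#' `A(C) = A_max C / (K_D + C)` by Levenberg-Marquardt, `K_D`
#' log-parameterized; used for the change of SPR dissociation amplitudes
#' with protein concentration.
#'
#' @param concentrations Analyte concentrations (strictly increasing).
#' @param amplitudes Reaction amplitudes at those concentrations.
#' @return A `binding_fit` with `A_max`, `K_D` (unit of `concentrations`).
#' @export
fit_amplitude_isotherm <- function(concentrations, amplitudes) {
  if (length(concentrations) < 4) abort("need at least 4 concentrations")
  df <- tibble(C = concentrations, A = amplitudes)
  start <- list(A_max = max(amplitudes),
                lk = log10(max(median(concentrations), 1e-9)))
  res <- nls_lm_fit(A ~ A_max * C / (10^lk + C), df, start)
  if (is.null(res))
    return(new_binding_fit("amplitude_isotherm", c(A_max = NA, K_D = NA),
                           c(A_max = NA, K_D = NA), NA_real_, nrow(df),
                           FALSE, df, NULL, "no_convergence"))
  K <- 10^res$coef[["lk"]]
  flags <- character(); converged <- TRUE
  if (K > max(concentrations)) { flags <- "no_saturation"; converged <- FALSE }
  new_binding_fit("amplitude_isotherm",
                  c(A_max = res$coef[["A_max"]], K_D = K),
                  c(A_max = res$se[["A_max"]],
                    K_D = log10_se(K, res$se[["lk"]])),
                  res$rss, nrow(df), converged, df, res$fitted, flags)
}

#' Fit an independent single-site ITC isotherm
#'
#' Least-squares fit of blank-subtracted per-injection heats to the
#' [itc_heats()] model (exact mass balance with volume-displacement
#' correction), estimating `K_D`, stoichiometry `n`, and `dH`. `K_D` is
#' log-parameterized; a small deterministic grid of `K_D` starts guards
#' against local minima. Experiments whose Wiseman c-value
#' `n * [cell] / K_D` falls outside `[1, 1000]` are flagged
#' `low_information`.
#'
#' @param heats Observed heats per injection, microcalories
#'   (blank-subtracted).
#' @param cell_conc,syringe_conc Concentrations, molar.
#' @param cell_volume_ul Cell volume, microlitres.
#' @param injection_volumes_ul Injection volumes, microlitres.
#' @return A `binding_fit` with `K_D` (molar), `n`, `dH` (kcal/mol).
#' @export
fit_itc <- function(heats, cell_conc, syringe_conc, cell_volume_ul = 170,
                    injection_volumes_ul = rep(2.43, length(heats))) {
  if (length(heats) < 10) abort("need at least 10 informative injections")
  stopifnot(length(injection_volumes_ul) == length(heats))
  df <- tibble(q = heats, i = seq_along(heats))
  model <- function(lk, n, dH)
    itc_heats(10^lk, n, dH, cell_conc, syringe_conc, cell_volume_ul,
              injection_volumes_ul)
  best <- NULL
  dH0 <- sum(heats) / (1e9 * cell_volume_ul * 1e-6 * cell_conc)
  if (!is.finite(dH0) || dH0 == 0) dH0 <- sign(sum(heats)) * 1
  for (lk0 in log10(cell_conc) + c(-2, -1, 0, 1)) {
    res <- nls_lm_fit(q ~ model(lk, n, dH), df,
                      start = list(lk = lk0, n = 1, dH = dH0),
                      lower = c(lk = log10(cell_conc) - 6, n = 0.05,
                                dH = -Inf),
                      upper = c(lk = log10(cell_conc) + 6, n = 20, dH = Inf))
    if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
  }
  if (is.null(best))
    return(new_binding_fit("itc", c(K_D = NA, n = NA, dH = NA),
                           c(K_D = NA, n = NA, dH = NA), NA_real_,
                           nrow(df), FALSE, df, NULL, "no_convergence"))
  K <- 10^best$coef[["lk"]]
  cval <- best$coef[["n"]] * cell_conc / K
  flags <- if (cval < 1 || cval > 1000) "low_information" else character()
  new_binding_fit("itc",
                  c(K_D = K, n = best$coef[["n"]], dH = best$coef[["dH"]]),
                  c(K_D = log10_se(K, best$se[["lk"]]),
                    n = best$se[["n"]], dH = best$se[["dH"]]),
                  best$rss, nrow(df), TRUE, df, best$fitted, flags)
}
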