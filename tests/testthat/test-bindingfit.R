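test_that("the anisotropy fitter inverts its own noiseless model", {
  d <- simulate_titration("anisotropy",
                          list(F_f = 0.05, F_b = 0.25, K_d_uM = 10),
                          noise_sd = 0)
  f <- fit_anisotropy(d)
  expect_true(f$converged)
  expect_equal(unname(f$estimates[["K_d"]]), 10, tolerance = 1e-6)
  expect_equal(unname(f$estimates[["F_f"]]), 0.05, tolerance = 1e-6)
  expect_equal(unname(f$estimates[["F_b"]]), 0.25, tolerance = 1e-6)
  # midpoint residual: F([L] = K_d) = (F_f + F_b) / 2 exactly
  mid <- anisotropy_model(10, 0.05, 0.25, 10)
  expect_equal(mid, (0.05 + 0.25) / 2)
})

test_that("anisotropy K_d recovery holds at 2% noise over replicates", {
  kds <- vapply(1:50, function(i) {
    d <- simulate_titration("anisotropy",
                            list(F_f = 0.05, F_b = 0.25, K_d_uM = 10),
                            noise_sd = 0.02 * 0.2, seed = i)
    unname(fit_anisotropy(d)$estimates[["K_d"]])
  }, 1)
  expect_lt(abs(median(kds) - 10) / 10, 0.10)
})

test_that("titrations without saturation are flagged unconverged", {
  d <- simulate_titration("anisotropy",
                          list(F_f = 0.05, F_b = 0.25, K_d_uM = 5000),
                          design = list(ligand_uM = c(0, 1, 2, 4, 8, 16)),
                          noise_sd = 0)
  f <- fit_anisotropy(d)
  expect_false(f$converged)
  expect_true("no_saturation" %in% f$flags)
})

test_that("the biexponential fitter handles the degenerate single-exponential", {
  d <- simulate_titration("spr_dissociation",
                          list(A_fast = 50, k_fast = 0.05, A_slow = 0,
                               k_slow = 0.001), noise_sd = 0)
  f <- fit_dissociation(d)
  expect_equal(unname(f$estimates[["k_fast"]]), 0.05, tolerance = 1e-3)
  expect_equal(unname(f$estimates[["A_fast"]] + f$estimates[["A_slow"]] *
                        (f$estimates[["k_slow"]] > 0.04)), 50,
               tolerance = 1e-2)
  expect_lt(f$rss, 1e-6)
})

test_that("planted biexponential parameters are recovered within 15% at 1% noise", {
  truth <- c(A_fast = 50, k_fast = 0.05, A_slow = 30, k_slow = 0.005)
  rel_err <- matrix(NA_real_, 20, 4, dimnames = list(NULL, names(truth)))
  for (i in 1:20) {
    d <- simulate_titration("spr_dissociation",
                            list(A_fast = 50, k_fast = 0.05, A_slow = 30,
                                 k_slow = 0.005),
                            noise_sd = 0.01 * 80, seed = i)
    f <- fit_dissociation(d)
    rel_err[i, ] <- abs(f$estimates[names(truth)] - truth) / truth
  }
  expect_true(all(apply(rel_err, 2, median) < 0.15))
})

test_that("biexponential components are always ordered k_fast > k_slow", {
  set.seed(31)
  for (i in 1:10) {
    p <- list(A_fast = runif(1, 10, 80), k_fast = 10^runif(1, -2, -1),
              A_slow = runif(1, 10, 80), k_slow = 10^runif(1, -3.5, -2.5))
    d <- simulate_titration("spr_dissociation", p, noise_sd = 0.3,
                            seed = 100 + i)
    f <- fit_dissociation(d)
    expect_gt(f$estimates[["k_fast"]], f$estimates[["k_slow"]])
  }
})

test_that("the 1:1 amplitude isotherm inverts exactly and at half-saturation", {
  conc <- c(0.05, 0.15, 0.5, 1.5, 5, 15, 50)    # the 50 nM - 50 uM design
  amp <- isotherm_model(conc, A_max = 120, K_D = 8)
  f <- fit_amplitude_isotherm(conc, amp)
  expect_equal(unname(f$estimates[["K_D"]]), 8, tolerance = 1e-6)
  expect_equal(unname(f$estimates[["A_max"]]), 120, tolerance = 1e-6)
  expect_equal(isotherm_model(8, 120, 8), 60)   # A(K_D) = A_max / 2
})

test_that("isotherm K_D recovery holds at 5% noise over the SPR design", {
  conc <- c(0.05, 0.1, 0.25, 0.5, 1, 2.5, 5, 10, 25, 50)
  kds <- vapply(1:50, function(i) {
    set.seed(200 + i)
    amp <- isotherm_model(conc, 120, 8) + rnorm(length(conc), 0, 0.05 * 120)
    unname(fit_amplitude_isotherm(conc, amp)$estimates[["K_D"]])
  }, 1)
  expect_lt(abs(median(kds) - 8) / 8, 0.20)
})

test_that("the ITC fitter inverts the 55 uM phosphopeptide design", {
  d <- simulate_titration("itc", list(K_D = 55e-6, n = 1, dH = -8),
                          design = list(cell_conc = 0.125e-3,
                                        syringe_conc = 2.5e-3), noise_sd = 0)
  f <- fit_itc(d$heat_ucal, cell_conc = 0.125e-3, syringe_conc = 2.5e-3)
  expect_equal(unname(f$estimates[["K_D"]]), 55e-6, tolerance = 1e-3)
  expect_equal(unname(f$estimates[["n"]]), 1, tolerance = 1e-3)
  expect_equal(unname(f$estimates[["dH"]]), -8, tolerance = 1e-3)
  expect_length(f$flags, 0)   # c-value ~2.3 is informative
})

test_that("zero enthalpy gives zero heats; extreme c-values are flagged", {
  q0 <- itc_heats(K_D = 1e-5, n = 1, dH = 0, cell_conc = 1e-4,
                  syringe_conc = 2e-3)
  expect_equal(q0, rep(0, 20))
  d <- simulate_titration("itc", list(K_D = 1e-3, n = 1, dH = -8),
                          design = list(cell_conc = 5e-5,
                                        syringe_conc = 1e-3), noise_sd = 0)
  f <- fit_itc(d$heat_ucal, cell_conc = 5e-5, syringe_conc = 1e-3)
  expect_true("low_information" %in% f$flags)
})

test_that("predicted ITC heats match numerical mass-balance integration", {
  for (p in list(list(K = 55e-6, n = 1, dH = -8, M = 0.125e-3, X = 2.5e-3),
                 list(K = 8e-6, n = 1, dH = -10, M = 0.075e-3, X = 2.5e-3),
                 list(K = 2e-4, n = 1.7, dH = 5, M = 2e-4, X = 4e-3))) {
    q_model <- itc_heats(p$K, p$n, p$dH, p$M, p$X)
    q_oracle <- itc_oracle_heats(p$K, p$n, p$dH, p$M, p$X)
    expect_lt(max(abs(q_model - q_oracle)) / max(abs(q_oracle)), 1e-6)
  }
})

test_that("cumulative ITC heat never exceeds the saturation bound", {
  for (K in c(1e-7, 1e-5, 1e-4)) {
    q <- itc_heats(K, n = 1.2, dH = -9, cell_conc = 1e-4,
                   syringe_conc = 3e-3)
    expect_lte(abs(sum(q)), abs(1.2 * -9 * 1e9 * 170e-6 * 1e-4))
  }
})

test_that("K_D units follow the concentration axis (uM vs M round trip)", {
  conc_uM <- c(0.5, 1, 2, 5, 10, 30, 60)
  amp <- isotherm_model(conc_uM, 100, 8)
  f_uM <- fit_amplitude_isotherm(conc_uM, amp)
  f_M <- fit_amplitude_isotherm(conc_uM * 1e-6, amp)
  expect_equal(unname(f_uM$estimates[["K_D"]]),
               unname(f_M$estimates[["K_D"]]) * 1e6, tolerance = 1e-6)
})

test_that("chemical-shift perturbations match hand-computed values", {
  free <- data.frame(residue = c("G10", "L11", "R90"),
                     d1H = c(8.0, 7.5, 9.1), d15N = c(110, 118, 124))
  bound <- data.frame(residue = c("G10", "L11", "R90"),
                      d1H = c(8.0, 7.6, 9.1), d15N = c(110, 118.5, 129))
  out <- shift_perturbation(free, bound)
  expect_equal(out$delta_delta[out$residue == "G10"], 0)
  expect_equal(out$delta_delta[out$residue == "L11"], sqrt(0.01 + 0.01))
  expect_equal(out$delta_delta[out$residue == "R90"], 1.0)  # 5/5 scaling
})

test_that("unpaired residues are dropped and reported, never zeroed", {
  free <- data.frame(residue = c("A1", "B2"), d1H = c(8, 8),
                     d15N = c(110, 112))
  bound <- data.frame(residue = c("A1", "C3"), d1H = c(8.2, 8),
                      d15N = c(111, 113))
  expect_warning(out <- shift_perturbation(free, bound), "B2")
  expect_equal(out$residue, "A1")
  expect_setequal(attr(out, "unmatched"), c("B2", "C3"))
})

test_that("binding fits expose broom-style tidy and glance", {
  d <- simulate_titration("anisotropy",
                          list(F_f = 0.05, F_b = 0.25, K_d_uM = 10),
                          noise_sd = 0.002, seed = 5)
  f <- fit_anisotropy(d)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("F_f", "F_b", "K_d"))
  expect_true(all(td$std.error >= 0))
  gl <- glance(f)
  expect_equal(gl$n, nrow(d))
  expect_true(gl$converged)
})
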