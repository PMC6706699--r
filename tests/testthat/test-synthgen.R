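test_that("a spec with no events yields a pure-noise movie and empty truth", {
  spec <- movie_spec(width = 48, height = 48, n_frames = 5,
                     nucleation_rate = 0, persistent_count = 0, seed = 1)
  mv <- simulate_movie(spec)
  expect_equal(nrow(mv$truth), 0)
  expect_equal(mean(mv$channels$master), spec$background_level,
               tolerance = 0.01)
  expect_equal(dim(mv$channels$slave), c(48, 48, 5))
})

test_that("noise-free rendering conserves the analytic Gaussian integral", {
  spec <- movie_spec(width = 64, height = 64, n_frames = 4,
                     nucleation_rate = 0, persistent_count = 2,
                     read_noise_sd = 0, poisson_noise = FALSE, seed = 7)
  mv <- simulate_movie(spec)
  A_sum <- sum(mv$truth$peak_amplitude)
  expected <- spec$background_level * 64 * 64 +
    2 * pi * spec$psf_sigma^2 * A_sum
  for (f in 1:4)
    expect_equal(sum(mv$channels$master[, , f]), expected,
                 tolerance = 1e-3)
})

test_that("generators are bit-identical under a fixed seed", {
  spec <- movie_spec(width = 48, height = 48, n_frames = 6, seed = 7)
  expect_identical(simulate_movie(spec), simulate_movie(spec))
  expect_identical(simulate_tracks(50, seed = 3), simulate_tracks(50, seed = 3))
  expect_identical(simulate_still(20, width = 128, height = 128, seed = 5),
                   simulate_still(20, width = 128, height = 128, seed = 5))
  expect_identical(
    simulate_titration("anisotropy", list(F_f = 0, F_b = 1, K_d_uM = 5),
                       noise_sd = 0.01, seed = 9),
    simulate_titration("anisotropy", list(F_f = 0, F_b = 1, K_d_uM = 5),
                       noise_sd = 0.01, seed = 9))
})

test_that("overcrowded scenes are refused with a crowding error", {
  expect_error(simulate_still(5000, width = 64, height = 64, seed = 1),
               class = "ccp_crowding_error")
  spec <- movie_spec(width = 32, height = 32, persistent_count = 500,
                     n_frames = 2)
  expect_error(simulate_movie(spec), class = "ccp_crowding_error")
})

test_that("movie spec invariants are enforced", {
  expect_error(movie_spec(frame_interval = 0), "frame_interval")
  expect_error(movie_spec(slave_positive_fraction = 1.2),
               "slave_positive_fraction")
  expect_error(movie_spec(nucleation_rate = -1), "non-negative")
})

test_that("persistent events span the acquisition; lifetimes are consistent", {
  spec <- movie_spec(width = 96, height = 96, n_frames = 40,
                     persistent_count = 3, nucleation_rate = 0.5, seed = 2)
  mv <- simulate_movie(spec)
  per <- mv$truth[mv$truth$category == "persistent", ]
  expect_true(all(per$birth == 0 & per$death == 39))
  oth <- mv$truth[mv$truth$category != "persistent", ]
  expect_true(all(oth$death - oth$birth + 1 ==
                    vapply(oth$trace, length, 1L)))
})

test_that("track tables plant the requested slave-positive fraction", {
  sim <- simulate_tracks(1000, slave_positive_fraction = 0.65, seed = 11)
  expect_lt(abs(mean(sim$truth$slave_positive) - 0.65),
            binom_ci_halfwidth(0.65, 1000))
  # degenerate ends of the fraction range
  sim0 <- simulate_tracks(100, slave_positive_fraction = 0, noise_sd = 5,
                          seed = 1)
  expect_true(all(!sim0$truth$slave_positive))
  expect_lt(abs(mean(sim0$tracks$slave)), 1)  # pure noise around zero
  sim1 <- simulate_tracks(100, slave_positive_fraction = 1, noise_sd = 0,
                          slave_amplitude_ratio = 0.8, seed = 2)
  expect_equal(sim1$tracks$slave, 0.8 * sim1$tracks$master)
})

test_that("planted fractions converge at large n (binomial CI at 1e4)", {
  sim <- simulate_tracks(10000, slave_positive_fraction = 0.31, seed = 4)
  expect_lt(abs(mean(sim$truth$slave_positive) - 0.31),
            binom_ci_halfwidth(0.31, 10000))
})

test_that("still generator honours co-occurrence and correlation settings", {
  st0 <- simulate_still(30, co_occurrence = c(sec = 0), width = 128,
                        height = 128, seed = 3)
  expect_true(all(!st0$truth$sec_positive))
  expect_equal(mean(st0$channels$sec), 100, tolerance = 0.02)
  st1 <- simulate_still(40, co_occurrence = c(sec = 1), width = 160,
                        height = 160, amplitude_correlation = 1,
                        read_noise_sd = 0, poisson_noise = FALSE, seed = 4)
  expect_equal(cor(st1$truth$amplitude, st1$truth$sec_amplitude), 1,
               tolerance = 1e-12)
  expect_error(simulate_still(10, co_occurrence = c(a = 1.4)), "co_occurrence")
})

test_that("titration generator matches its models at key points", {
  # anisotropy at [L] = K_d sits exactly at the half-saturation midpoint
  d <- simulate_titration("anisotropy",
                          list(F_f = 0.06, F_b = 0.22, K_d_uM = 10),
                          design = list(ligand_uM = c(0, 5, 10, 20, 40)),
                          noise_sd = 0)
  expect_equal(d$anisotropy[d$ligand_uM == 10], (0.06 + 0.22) / 2)
  # zero slow amplitude degenerates to a single exponential
  d2 <- simulate_titration("spr_dissociation",
                           list(A_fast = 40, k_fast = 0.03, A_slow = 0,
                                k_slow = 0.004), noise_sd = 0)
  expect_equal(d2$response, 40 * exp(-0.03 * d2$time_s))
  expect_error(simulate_titration("nmr", list()), "unknown")
})

test_that("saturating noiseless ITC heats integrate to n*dH*cell moles", {
  # strong binding, titrant excess in the very first injection, and a cell
  # large enough that displacement losses are negligible
  q <- itc_heats(K_D = 1e-9, n = 1, dH = -10, cell_conc = 1e-4,
                 syringe_conc = 5e-2, cell_volume_ul = 1000)
  lim <- -10 * 1e9 * 1000e-6 * 1e-4  # n * dH * initial cell moles, ucal
  expect_equal(sum(q), lim, tolerance = 0.01)
  expect_lte(abs(sum(q)), abs(lim))  # displacement losses stay below limit
})
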