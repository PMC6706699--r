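stationary_dets <- function(n_frames, x, y, amplitude = 100, drop = integer()) {
  d <- tibble::tibble(frame = rep(0:(n_frames - 1), each = length(x)),
                      x = rep(x, n_frames) , y = rep(y, n_frames),
                      amplitude = amplitude)
  d[!(d$frame %in% drop), ]
}

test_that("a single stationary spot links into one full-length track", {
  lk <- link_tracks(stationary_dets(50, 5, 5))
  expect_equal(length(unique(lk$track_id)), 1)
  expect_equal(nrow(lk), 50)
})

test_that("well-separated spots never swap identities", {
  lk <- link_tracks(stationary_dets(30, c(5, 25), c(5, 5)))
  expect_equal(length(unique(lk$track_id)), 2)
  for (id in unique(lk$track_id))
    expect_equal(var(lk$x[lk$track_id == id]), 0)
})

test_that("gap closing bridges a single-frame dropout", {
  lk <- link_tracks(stationary_dets(20, 5, 5, drop = 10), max_gap = 2)
  expect_equal(length(unique(lk$track_id)), 1)
  lk0 <- link_tracks(stationary_dets(20, 5, 5, drop = 10), max_gap = 0)
  expect_equal(length(unique(lk0$track_id)), 2)
})

test_that("classification partitions tracks with the stated rules", {
  tracks <- dplyr::bind_rows(
    tibble::tibble(track_id = 1, frame = 0:19, amplitude = 5),    # spans all
    tibble::tibble(track_id = 2, frame = 3:6, amplitude = 8),     # low, short
    tibble::tibble(track_id = 3, frame = 2:11, amplitude = 80))   # bright
  cl <- classify_tracks(tracks, n_frames = 20, frame_interval = 2,
                        intensity_threshold = 50)
  expect_equal(cl$category[cl$track_id == 1], "persistent")  # amplitude moot
  expect_equal(cl$category[cl$track_id == 2], "transient")
  expect_equal(cl$category[cl$track_id == 3], "bona_fide")
  expect_equal(sort(table(cl$category))[["persistent"]], 1)
  expect_equal(sum(table(cl$category)), nrow(cl))            # partition
  expect_equal(cl$lifetime_s[cl$track_id == 3], 20)
  expect_error(classify_tracks(tracks, 20, 2, intensity_threshold = 0),
               "threshold")
})

test_that("planted populations are categorized correctly at the generator separation", {
  sim <- simulate_tracks(400, seed = 6)
  tr <- dplyr::rename(sim$tracks, amplitude = master)
  cl <- classify_tracks(tr, n_frames = .Machine$integer.max,
                        frame_interval = 2, intensity_threshold = 50)
  agree <- mean(cl$category[order(cl$track_id)] ==
                  sim$truth$category[order(sim$truth$track_id)])
  expect_gte(agree, 0.95)
})

test_that("slave positivity follows the significant-frame fraction rule", {
  tr <- tibble::tibble(track_id = rep(1:3, each = 10),
                       slave_significant = c(rep(TRUE, 10), rep(FALSE, 10),
                                             rep(c(TRUE, FALSE), c(4, 6))))
  pos <- slave_positivity(tr, min_significant_fraction = 0.3)
  expect_equal(pos$slave_positive, c(TRUE, FALSE, TRUE))
  pos5 <- slave_positivity(tr, min_significant_fraction = 0.5)
  expect_equal(pos5$slave_positive, c(TRUE, FALSE, FALSE))
})

test_that("a planted 65% positive fraction is recovered through flagging", {
  sim <- simulate_tracks(800, slave_positive_fraction = 0.65, seed = 13)
  tr <- flag_slave_frames(sim$tracks, alpha = 0.05, noise_sd = 10)
  cl <- classify_tracks(dplyr::rename(tr, amplitude = master),
                        n_frames = .Machine$integer.max, frame_interval = 2,
                        intensity_threshold = 50)
  bona <- cl$track_id[cl$category == "bona_fide"]
  pos <- slave_positivity(dplyr::filter(tr, track_id %in% bona))
  expect_lt(abs(mean(pos$slave_positive) - 0.65),
            binom_ci_halfwidth(0.65, length(bona)) + 0.02)
})

test_that("lifetime statistics match the closed form on 1..100 s", {
  ls <- lifetime_stats(1:100)
  p95 <- quantile(1:100, 0.95, names = FALSE)   # 95.05
  expect_equal(ls$p95_s, p95)
  expect_equal(ls$p95_mean_s, mean(96:100))     # = 98
  expect_equal(ls$mean_s, 50.5)
  expect_equal(lifetime_stats(rep(40, 25))$p95_mean_s, 40)
  expect_error(lifetime_stats(1:10), "at least 20")
})

test_that("a two-population lifetime mixture is detectably bimodal", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(14)
  lt <- c(rnorm(150, 8, 1.5), rnorm(150, 60, 8))
  mc <- Mclust(lt, G = 1:2, verbose = FALSE)
  expect_equal(mc$G, 2)
  expect_lt(max(abs(sort(mc$parameters$mean) - c(8, 60))), 3)
})

test_that("persistent density is count over area", {
  expect_equal(persistent_density(0, 100), 0)
  expect_equal(persistent_density(10, 100), 0.1)
  expect_error(persistent_density(1, 0), "area")
})

test_that("cohort traces recover the generative profile and SE conventions", {
  # identical noiseless tracks: SE identically zero
  prof <- c(seq(20, 100, length.out = 6), rep(100, 10),
            seq(100, 20, length.out = 4))
  tracks <- dplyr::bind_rows(lapply(1:8, function(i)
    tibble::tibble(track_id = i, frame = seq_along(prof) - 1,
                   channel = "master", amplitude = prof)))
  cl <- classify_tracks(dplyr::filter(tracks, channel == "master"),
                        n_frames = 1000, frame_interval = 2,
                        intensity_threshold = 50)
  co <- cohort_traces(tracks, cl, cohort_bounds = list(c(20, 60)))
  expect_true(all(co$se == 0))
  expect_equal(co$n_tracks[1], 8)
  # mean trace follows the planted rise-plateau-fall within noise / sqrt(n)
  set.seed(15)
  noisy <- dplyr::bind_rows(lapply(1:40, function(i)
    tibble::tibble(track_id = i, frame = seq_along(prof) - 1,
                   channel = "master",
                   amplitude = prof + rnorm(length(prof), 0, 10))))
  cln <- classify_tracks(noisy, n_frames = 1000, frame_interval = 2,
                         intensity_threshold = 50)
  con <- cohort_traces(noisy, cln, cohort_bounds = list(c(20, 60)))
  ref <- approx(seq(0, 1, length.out = length(prof)), prof,
                xout = seq(0, 1, length.out = 50))$y
  expect_lt(max(abs(con$mean - ref)), 5 * 10 / sqrt(40))
  # single-track cohort: mean = the track, SE = 0 by convention
  one <- tibble::tibble(track_id = 1, frame = seq_along(prof) - 1,
                        channel = "master", amplitude = prof)
  co1 <- cohort_traces(one, classify_tracks(one, 1000, 2, 50),
                       cohort_bounds = list(c(20, 60)))
  expect_true(all(co1$se == 0))
  expect_equal(co1$mean,
               approx(seq(0, 1, length.out = length(prof)), prof,
                      xout = seq(0, 1, length.out = 50))$y)
  # empty cohort: no rows, not an error
  expect_equal(nrow(cohort_traces(one, classify_tracks(one, 1000, 2, 50),
                                  cohort_bounds = list(c(200, 300)))), 0)
  expect_error(cohort_traces(one, cl, cohort_bounds = list(c(40, 20))),
               "bounds")
})

test_that("cohort track counts conserve the bona fide population", {
  sim <- simulate_tracks(300, seed = 16)
  tr <- sim$tracks |> dplyr::rename(amplitude = master) |>
    dplyr::mutate(channel = "master")
  cl <- classify_tracks(tr, n_frames = .Machine$integer.max,
                        frame_interval = 2, intensity_threshold = 50)
  bounds <- list(c(0, 20), c(20, 40), c(40, 80), c(80, 1e6))
  co <- cohort_traces(tr, cl, cohort_bounds = bounds)
  per_cohort <- co |> dplyr::distinct(cohort, n_tracks)
  expect_equal(sum(per_cohort$n_tracks),
               sum(cl$category == "bona_fide"))
})
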