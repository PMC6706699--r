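default_config <- function() {
  list(seed = 1L,
       frame_interval = 2,
       detection = list(psf_sigma = 1.1, alpha = 0.05, window_radius = 4,
                        slave_search_radius = 2),
       tracking = list(max_displacement = 3, max_gap = 2),
       classification = list(intensity_threshold = 50, min_frames = 4),
       positivity = list(min_significant_fraction = 0.3),
       binning = list(n_bins = 10),
       cohorts = list(c(20, 40), c(40, 60), c(60, 80), c(80, 120)))
}

merge_config <- function(config) {
  base <- default_config()
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(config[[nm]])))
      base[[nm]] <- utils::modifyList(base[[nm]], config[[nm]])
    else base[[nm]] <- config[[nm]]
  }
  base
}

config_detection <- function(cfg) do.call(detection_config, cfg$detection)

provenance_block <- function(cfg) {
  list(config_hash = rlang::hash(cfg), seed = cfg$seed,
       package_version = as.character(utils::packageVersion("ccptools")),
       r_version = R.version.string)
}

condition_movies <- function(cond, cfg, cond_index) {
  if (!is.null(cond$movies) && is.list(cond$movies) &&
      inherits(cond$movies[[1]], "ccp_movie")) return(cond$movies)
  if (!is.null(cond$tiff)) {
    return(lapply(cond$tiff, function(paths)
      read_movie_tiff(unlist(paths), frame_interval = cfg$frame_interval)))
  }
  n <- cond$n_movies %||% 1L
  lapply(seq_len(n), function(i) {
    spec_args <- cond$movie_spec %||% list()
    spec_args$frame_interval <- spec_args$frame_interval %||%
      cfg$frame_interval
    spec_args$seed <- (cfg$seed %||% 1L) + 1000L * cond_index + i
    simulate_movie(do.call(movie_spec, spec_args))
  })
}

analyze_one_movie <- function(movie, cfg, cell_id) {
  dcfg <- config_detection(cfg)
  dets <- detect_movie(movie, dcfg)
  master_name <- names(movie$channels)[1]
  masters <- filter(dets, .data$channel == master_name)
  slaves <- filter(dets, .data$channel != master_name)
  linked <- link_tracks(select(masters, all_of(c("frame", "x", "y",
                                                 "amplitude"))),
                        max_displacement = cfg$tracking$max_displacement,
                        max_gap = cfg$tracking$max_gap)
  n_frames <- dim(movie$channels[[1]])[3]
  classified <- if (nrow(linked)) classify_tracks(
    linked, n_frames = n_frames, frame_interval = movie$frame_interval,
    intensity_threshold = cfg$classification$intensity_threshold,
    min_frames = cfg$classification$min_frames) else
      tibble(track_id = integer(), first = integer(), last = integer(),
             n_obs = integer(), max_amplitude = numeric(),
             lifetime_s = numeric(), category = character())
  # attach the slave significance of the detection each track frame came
  # from (masters and slave rows are ordered 1:1 within a frame)
  tracks_long <- linked
  if (nrow(slaves) && nrow(linked)) {
    key <- slaves |>
      mutate(x = .data$master_x, y = .data$master_y) |>
      select(all_of(c("frame", "x", "y", "significant", "amplitude")))
    names(key)[4:5] <- c("slave_significant", "slave_amplitude")
    tracks_long <- left_join(linked, key, by = c("frame", "x", "y"))
    tracks_long$slave_significant <-
      tracks_long$slave_significant %in% TRUE
  } else tracks_long$slave_significant <- FALSE
  bona <- filter(classified, .data$category == "bona_fide")
  pos <- if (nrow(bona)) {
    slave_positivity(filter(tracks_long, .data$track_id %in% bona$track_id),
                     cfg$positivity$min_significant_fraction)
  } else tibble(track_id = integer(), significant_fraction = numeric(),
                slave_positive = logical())
  area <- field_area_um2(movie)
  lstats <- if (nrow(bona) >= 20) lifetime_stats(bona$lifetime_s) else
    tibble(n = nrow(bona), mean_s = NA_real_, p95_s = NA_real_,
           p95_mean_s = NA_real_)
  summary <- tibble(cell_id = cell_id,
                    n_tracks = nrow(classified),
                    n_bona_fide = sum(classified$category == "bona_fide"),
                    n_transient = sum(classified$category == "transient"),
                    n_persistent = sum(classified$category == "persistent"),
                    persistent_density_um2 = persistent_density(
                      sum(classified$category == "persistent"), area),
                    p95_mean_s = lstats$p95_mean_s,
                    mean_lifetime_s = lstats$mean_s,
                    slave_positive_pct = if (nrow(pos))
                      100 * mean(pos$slave_positive) else NA_real_)
  list(summary = summary, detections = dets, tracks = tracks_long,
       classified = classified, positivity = pos)
}

#' Run the end-to-end movie analysis pipeline
#'
#' Simulates (or loads) the movies of each condition, detects master and
#' slave channels, links tracks, classifies them, and reports per-cell and
#' per-condition statistics: bona fide/persistent counts, persistent
#' density, 95th-percentile lifetime statistic, slave-positive percentage,
#' and cohort traces; condition pairs are compared with Welch t-tests.
#' Deterministic given the config (and its seed). Intermediate tables are
#' written as CSV and the report as JSON when `out_dir` is set.
#'
#' @param config Configuration list (or YAML path): `seed`, optional
#'   `out_dir`, `frame_interval`, `detection`, `tracking`,
#'   `classification`, `positivity`, `cohorts`, and `conditions` — a list
#'   of `list(name =, n_movies =, movie_spec = list(...))` entries (or
#'   in-memory `movies`, or `tiff` path sets).
#' @return List of class `ccp_report`: `per_cell`, `comparisons`,
#'   `cohorts` (per condition), `provenance`.
#' @export
run_movie_analysis <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(config)
  if (is.null(cfg$conditions)) abort("config$conditions is required")
  per_cell <- list(); cohorts <- list()
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[[ci]]
    name <- cond$name %||% paste0("condition", ci)
    movies <- condition_movies(cond, cfg, ci)
    for (mi in seq_along(movies)) {
      cell_id <- sprintf("%s_cell%02d", name, mi)
      res <- tryCatch(analyze_one_movie(movies[[mi]], cfg, cell_id),
                      error = function(e)
                        abort(sprintf("stage movie_analysis failed for %s: %s",
                                      cell_id, conditionMessage(e))))
      res$summary$condition <- name
      per_cell[[length(per_cell) + 1L]] <- res$summary
      if (!is.null(cfg$out_dir)) {
        write_csv_quiet(res$detections,
                        file.path(cfg$out_dir, paste0(cell_id,
                                                      "_detections.csv")))
        write_csv_quiet(res$tracks,
                        file.path(cfg$out_dir, paste0(cell_id,
                                                      "_tracks.csv")))
      }
      co <- cohort_traces(
        res$tracks |> mutate(channel = "master") |>
          select(all_of(c("track_id", "frame", "channel", "amplitude"))),
        res$classified, cohort_bounds = cfg$cohorts)
      if (nrow(co)) {
        co$condition <- name; co$cell_id <- cell_id
        cohorts[[length(cohorts) + 1L]] <- co
      }
    }
  }
  per_cell <- bind_rows(per_cell)
  comparisons <- list()
  cond_names <- unique(per_cell$condition)
  if (length(cond_names) == 2) {
    for (stat in c("persistent_density_um2", "p95_mean_s",
                   "slave_positive_pct")) {
      vals <- tibble(condition = per_cell$condition,
                     value = per_cell[[stat]]) |>
        filter(is.finite(.data$value))
      if (all(table(vals$condition) >= 2) &&
          dplyr::n_distinct(vals$condition) == 2) {
        cmp <- tryCatch(summarize_condition(vals),
                        error = function(e) NULL)  # e.g. zero variance
        if (!is.null(cmp)) {
          cmp$statistic <- stat
          comparisons[[length(comparisons) + 1L]] <- cmp
        }
      }
    }
  }
  report <- structure(
    list(per_cell = per_cell, comparisons = bind_rows(comparisons),
         cohorts = if (length(cohorts)) bind_rows(cohorts) else NULL,
         provenance = provenance_block(cfg)),
    class = "ccp_report")
  if (!is.null(cfg$out_dir)) {
    write_csv_quiet(per_cell, file.path(cfg$out_dir, "per_cell.csv"))
    if (nrow(report$comparisons))
      write_csv_quiet(report$comparisons,
                      file.path(cfg$out_dir, "comparisons.csv"))
    jsonlite::write_json(
      list(per_cell = per_cell, comparisons = report$comparisons,
           provenance = report$provenance),
      file.path(cfg$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Run the immunofluorescence still-image analysis
#'
#' Detects master spots in each still, measures each secondary channel at
#' the master positions, and reports per-cell Pearson correlations and the
#' pooled equal-count proportion curve per secondary channel.
#'
#' @param config List (or YAML path) with `seed`, optional `out_dir`,
#'   `detection`, `binning`, and `stills`: a list of `ccp_still` objects
#'   (or `list(n_spots =, co_occurrence =, ...)` specs to simulate).
#' @return List of class `ccp_if_report`: `per_cell` (PCC and counts per
#'   cell and secondary channel), `curves` (proportion curves),
#'   `provenance`.
#' @export
run_if_analysis <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(config)
  if (is.null(cfg$stills)) abort("config$stills is required")
  stills <- cfg$stills
  if (!inherits(stills[[1]], "ccp_still"))
    stills <- lapply(seq_along(stills), function(i) {
      args <- stills[[i]]
      args$seed <- args$seed %||% ((cfg$seed %||% 1L) + i)
      do.call(simulate_still, args)
    })
  dcfg <- config_detection(cfg)
  per_cell <- list(); paired_all <- list()
  for (i in seq_along(stills)) {
    st <- stills[[i]]
    cell_id <- sprintf("cell%02d", i)
    masters <- detect_frame(st$channels[[1]], dcfg)
    for (ch in names(st$channels)[-1]) {
      sl <- measure_slave(masters, st$channels[[ch]], dcfg)
      paired <- tibble(cell_id = cell_id, channel = ch,
                       master_intensity = masters$amplitude,
                       slave_intensity = sl$amplitude,
                       slave_significant = sl$significant)
      paired_all[[length(paired_all) + 1L]] <- paired
      per_cell[[length(per_cell) + 1L]] <- tibble(
        cell_id = cell_id, channel = ch, n_detections = nrow(masters),
        pcc = if (nrow(masters) >= 2) pearson_cc(paired$master_intensity,
                                                 paired$slave_intensity)
              else NA_real_,
        positive_pct = 100 * mean(paired$slave_significant))
    }
  }
  paired_all <- bind_rows(paired_all)
  curves <- paired_all |> group_by(.data$channel) |>
    dplyr::group_map(function(df, key) {
      cv <- proportion_curve(df, n_bins = cfg$binning$n_bins)
      cv$channel <- key$channel
      cv
    }) |> bind_rows()
  report <- structure(list(per_cell = bind_rows(per_cell), curves = curves,
                           provenance = provenance_block(cfg)),
                      class = "ccp_if_report")
  if (!is.null(cfg$out_dir)) {
    write_csv_quiet(report$per_cell, file.path(cfg$out_dir,
                                               "if_per_cell.csv"))
    write_csv_quiet(curves, file.path(cfg$out_dir,
                                      "if_proportion_curves.csv"))
  }
  report
}

#' Fit a folder (or list) of binding titrations
#'
#' @param config List (or YAML path) with `titrations`: a list of
#'   `list(kind =, file =)` or `list(kind =, data =)` entries plus
#'   kind-specific fields (`cell_conc`, `syringe_conc`, `cell_volume_ul`
#'   for ITC); optional `out_dir`.
#' @return List of class `ccp_binding_report`: `fits` (named list of
#'   `binding_fit`s), `summary` (tidy estimates), `provenance`.
#' @export
run_binding_suite <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(config)
  if (is.null(cfg$titrations)) abort("config$titrations is required")
  fits <- list()
  for (i in seq_along(cfg$titrations)) {
    tt <- cfg$titrations[[i]]
    data <- if (!is.null(tt$data)) as_tibble(tt$data) else
      as_tibble(read.csv(tt$file))
    fit <- switch(tt$kind,
      anisotropy = fit_anisotropy(data),
      spr_dissociation = fit_dissociation(data),
      amplitude_isotherm = fit_amplitude_isotherm(data[[1]], data[[2]]),
      itc = fit_itc(data$heat_ucal, cell_conc = tt$cell_conc,
                    syringe_conc = tt$syringe_conc,
                    cell_volume_ul = tt$cell_volume_ul %||% 170,
                    injection_volumes_ul = tt$injection_volumes_ul %||%
                      rep(2.43, nrow(data))),
      abort(sprintf("unknown titration kind '%s'", tt$kind)))
    fits[[tt$name %||% paste0(tt$kind, "_", i)]] <- fit
  }
  summary <- imap(fits, function(f, nm) {
    td <- tidy(f); td$fit <- nm; td$model <- f$model
    td$converged <- f$converged
    td
  }) |> bind_rows()
  report <- structure(list(fits = fits, summary = summary,
                           provenance = provenance_block(cfg)),
                      class = "ccp_binding_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(summary = summary,
           fits = lapply(fits, function(f)
             list(model = f$model, estimates = as.list(f$estimates),
                  se = as.list(f$se), rss = f$rss, n = f$n,
                  converged = f$converged, flags = f$flags)),
           provenance = report$provenance),
      file.path(cfg$out_dir, "binding_fits.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.ccp_report <- function(x, ...) {
  cat("<ccp_report>\n")
  print(x$per_cell)
  if (!is.null(x$comparisons) && nrow(x$comparisons)) {
    cat("\nCondition comparisons (Welch t):\n")
    print(x$comparisons)
  }
  invisible(x)
}
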