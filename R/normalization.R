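ref_probs <- function(n_quantiles = 99L) seq_len(n_quantiles) / (n_quantiles + 1)

check_cells <- function(cells) {
  stopifnot(all(c("cell_id", "intensity") %in% names(cells)))
  bad <- cells |> group_by(.data$cell_id) |>
    summarise(n = sum(is.finite(.data$intensity))) |>
    filter(.data$n < 20)
  if (nrow(bad))
    abort(paste("cells with fewer than 20 finite intensities:",
                paste(bad$cell_id, collapse = ", ")))
  invisible(cells)
}

#' Build the median reference intensity distribution across cells
#'
#' Operationalizes each cell's cumulative intensity distribution as an
#' empirical quantile table on a fixed grid (default 99 percentiles,
#' 1..99), and takes the reference at each grid point as the median across
#' cells of that cell's quantile. The reference is non-decreasing by
#' construction.
#'
#' @param cells Tibble with `cell_id` and `intensity` (one channel); at
#'   least 3 cells with at least 20 finite intensities each.
#' @param n_quantiles Number of grid points.
#' @return Tibble with `prob` and `value`.
#' @export
build_reference <- function(cells, n_quantiles = 99L) {
  check_cells(cells)
  if (dplyr::n_distinct(cells$cell_id) < 3)
    abort("need at least 3 cells to build a reference distribution")
  probs <- ref_probs(n_quantiles)
  qs <- cells |> group_by(.data$cell_id) |>
    dplyr::reframe(prob = probs,
                   q = quantile(.data$intensity, probs, names = FALSE,
                                type = 7))
  qs |> group_by(.data$prob) |>
    summarise(value = median(.data$q), .groups = "drop")
}

#' Scale factor matching a cell's intensity distribution to the reference
#'
#' Minimizes the mean squared error between the scaled cell quantile table
#' and the reference over the same grid:
#' `argmin_s sum_q (s Q_cell(q) - Q_ref(q))^2`, with the closed form
#' `s = sum(Q_ref Q_cell) / sum(Q_cell^2)`.
#'
#' @param intensities A cell's detection intensities (>= 20 finite values).
#' @param reference Reference tibble from [build_reference()].
#' @return Positive scale factor.
#' @export
fit_scale <- function(intensities, reference) {
  intensities <- intensities[is.finite(intensities)]
  if (length(intensities) < 20) abort("need >= 20 finite intensities")
  qc <- quantile(intensities, reference$prob, names = FALSE, type = 7)
  if (all(qc == 0)) abort("all-zero cell intensities: scale undefined")
  sum(reference$value * qc) / sum(qc^2)
}

#' Normalize per-cell CCP intensities onto the median reference
#'
#' Builds (or takes) the reference distribution and appends the fitted
#' per-cell scale factor and the scaled intensities.
#'
#' @param cells Tibble with `cell_id`, `intensity`.
#' @param reference Optional precomputed reference (from another channel or
#'   condition); defaults to the reference built from `cells` itself.
#' @return `cells` with added `scale` and `normalized` columns; the
#'   reference is attached as attribute `reference`.
#' @export
normalize_cells <- function(cells, reference = NULL) {
  check_cells(cells)
  reference <- reference %||% build_reference(cells)
  out <- cells |> group_by(.data$cell_id) |>
    mutate(scale = fit_scale(.data$intensity, reference)) |>
    ungroup() |>
    mutate(normalized = .data$intensity * .data$scale)
  attr(out, "reference") <- reference
  out
}
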