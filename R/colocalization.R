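#' Pearson correlation of paired master/slave intensities
#'
#' Standard sample Pearson correlation coefficient of the paired intensity
#' values of two CCP components measured at the same detections.
#'
#' @param master,slave Equal-length numeric vectors (>= 2 pairs).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_cc <- function(master, slave) {
  if (length(master) != length(slave)) abort("paired vectors must match")
  keep <- is.finite(master) & is.finite(slave)
  master <- master[keep]; slave <- slave[keep]
  if (length(master) < 2) abort("need at least 2 finite pairs")
  if (var(master) == 0 || var(slave) == 0)
    abort("PCC undefined: zero variance in one channel")
  cor(master, slave)
}

#' Proportion of slave-significant detections per master-intensity bin
#'
#' Sorts master detections by intensity (stable: ties keep input order),
#' splits them into `n_bins` equal-count bins (any remainder spread over
#' the lowest-intensity bins), and reports per bin the proportion of
#' detections whose slave signal is significant. The significance flag is
#' computed upstream with one shared threshold, so curves for different
#' conditions are directly comparable.
#'
#' @param paired Tibble with `master_intensity` and logical
#'   `slave_significant` (length >= `5 * n_bins`).
#' @param n_bins Number of equal-count bins (>= 2).
#' @return Tibble of class `ccp_proportion_curve`: `bin`, `bin_center`
#'   (mean master intensity), `bin_lo`, `bin_hi`, `count`,
#'   `proportion_positive`.
#' @export
proportion_curve <- function(paired, n_bins = 10) {
  stopifnot(all(c("master_intensity", "slave_significant") %in%
                  names(paired)))
  if (n_bins < 2) abort("n_bins must be >= 2")
  n <- nrow(paired)
  if (n < 5 * n_bins)
    abort(sprintf("need at least 5 * n_bins = %d detections, got %d",
                  5 * n_bins, n))
  ord <- order(paired$master_intensity)   # stable sort, ties by index
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin <- rep.int(seq_len(n_bins), sizes)
  out <- tibble(bin = bin,
                master_intensity = paired$master_intensity[ord],
                slave_significant = paired$slave_significant[ord]) |>
    group_by(.data$bin) |>
    summarise(bin_center = mean(.data$master_intensity),
              bin_lo = min(.data$master_intensity),
              bin_hi = max(.data$master_intensity),
              count = dplyr::n(),
              proportion_positive = mean(.data$slave_significant),
              .groups = "drop")
  class(out) <- c("ccp_proportion_curve", class(out))
  out
}

#' Compare a per-cell statistic between two conditions
#'
#' Mean and SD per condition with a two-tailed unpaired (Welch) t-test.
#'
#' @param per_cell Tibble with `condition` (exactly 2 levels, >= 2 cells
#'   each) and `value` (one statistic per cell).
#' @return One-row tibble: conditions, per-condition `n`, `mean`, `sd`,
#'   and `t_statistic`, `df`, `p_value`.
#' @export
summarize_condition <- function(per_cell) {
  stopifnot(all(c("condition", "value") %in% names(per_cell)))
  conds <- unique(per_cell$condition)
  if (length(conds) != 2) abort("exactly two conditions required")
  a <- per_cell$value[per_cell$condition == conds[1]]
  b <- per_cell$value[per_cell$condition == conds[2]]
  if (length(a) < 2 || length(b) < 2)
    abort("need at least 2 cells per condition")
  tt <- t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  tibble(condition_a = as.character(conds[1]),
         condition_b = as.character(conds[2]),
         n_a = length(a), n_b = length(b),
         mean_a = mean(a), sd_a = sd(a),
         mean_b = mean(b), sd_b = sd(b),
         t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}
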