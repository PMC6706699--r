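#' Simulate a binding titration
#'
#' Forward-simulates one of the three binding experiments with additive
#' Gaussian noise on the observed quantity: an equilibrium fluorescence
#' anisotropy titration, an SPR dissociation phase, or an ITC injection
#' series (default design: 20 injections of 2.43 ul into a 170 ul cell).
#'
#' @param kind One of `"anisotropy"`, `"spr_dissociation"`, `"itc"`.
#' @param true_params Named list of model parameters:
#'   anisotropy `F_f`, `F_b`, `K_d_uM`;
#'   spr_dissociation `A_fast`, `k_fast`, `A_slow`, `k_slow`;
#'   itc `K_D` (molar), `n`, `dH` (kcal/mol).
#' @param design Named list describing the measurement schedule:
#'   anisotropy `ligand_uM` (default 24 points, 0-200 uM);
#'   spr_dissociation `t_max_s` (default 510), `dt_s` (default 1);
#'   itc `cell_conc`, `syringe_conc` (molar), `cell_volume_ul` (170),
#'   `injection_volumes_ul` (20 x 2.43).
#' @param noise_sd Gaussian noise SD on the response (same unit as the
#'   response: anisotropy units, RU, or ucal).
#' @param seed Integer seed.
#' @return A tibble; x column named per kind (`ligand_uM`, `time_s`, or
#'   `injection_index`), response column `anisotropy`, `response`, or
#'   `heat_ucal`.
#' @export
simulate_titration <- function(kind, true_params, design = list(),
                               noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  out <- switch(kind,
    anisotropy = {
      p <- true_params
      stopifnot(p$K_d_uM > 0)
      L <- design$ligand_uM %||% c(0, 2^seq(-2, 7.5, by = 0.4))
      tibble(ligand_uM = L,
             anisotropy = anisotropy_model(L, p$F_f, p$F_b, p$K_d_uM))
    },
    spr_dissociation = {
      p <- true_params
      stopifnot(p$k_fast >= 0, p$k_slow >= 0)
      t <- seq(0, design$t_max_s %||% 510, by = design$dt_s %||% 1)
      tibble(time_s = t,
             response = biexp_model(t, p$A_fast, p$k_fast, p$A_slow, p$k_slow))
    },
    itc = {
      p <- true_params
      stopifnot(p$K_D > 0)
      vols <- design$injection_volumes_ul %||% rep(2.43, 20)
      q <- itc_heats(p$K_D, p$n, p$dH,
                     cell_conc = design$cell_conc,
                     syringe_conc = design$syringe_conc,
                     cell_volume_ul = design$cell_volume_ul %||% 170,
                     injection_volumes_ul = vols)
      tibble(injection_index = seq_along(q), heat_ucal = q)
    },
    abort(sprintf("unknown titration kind '%s'", kind)))
  ycol <- names(out)[2]
  if (noise_sd > 0) out[[ycol]] <- out[[ycol]] + rnorm(nrow(out), 0, noise_sd)
  attr(out, "kind") <- kind
  out
}
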