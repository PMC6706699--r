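#' Single-site anisotropy binding model
#'
#' `F = F_f + (F_b - F_f) * [L] / (K_d + [L])`, the anisotropy of a mixture
#' of free and bound fluorescent peptide under pseudo-first-order ligand
#' concentration `[L]`.
#'
#' @param L Ligand concentration (any unit; `K_d` is returned in the same).
#' @param F_f,F_b Anisotropy of the free and bound peptide.
#' @param K_d Equilibrium dissociation constant.
#' @return Predicted anisotropy.
#' @export
anisotropy_model <- function(L, F_f, F_b, K_d) {
  F_f + (F_b - F_f) * L / (K_d + L)
}

#' Biexponential dissociation model
#'
#' `R(t) = A_fast * exp(-k_fast t) + A_slow * exp(-k_slow t)`, the
#' double-exponential decay used for SPR dissociation phases with fast and
#' slow components.
#'
#' @param t Time, seconds.
#' @param A_fast,A_slow Amplitudes (response units).
#' @param k_fast,k_slow Rate constants, 1/s.
#' @return Predicted response.
#' @export
biexp_model <- function(t, A_fast, k_fast, A_slow, k_slow) {
  A_fast * exp(-k_fast * t) + A_slow * exp(-k_slow * t)
}

#' Simple 1:1 amplitude isotherm
#'
#' `A(C) = A_max * C / (K_D + C)`: the hyperbolic dependence of a reaction
#' amplitude on analyte concentration for 1:1 binding.
#'
#' @param C Concentration (unit of `K_D`).
#' @param A_max Saturating amplitude.
#' @param K_D Apparent equilibrium dissociation constant.
#' @return Predicted amplitude.
#' @export
isotherm_model <- function(C, A_max, K_D) {
  A_max * C / (K_D + C)
}

#' Predicted per-injection ITC heats for an independent single-site model
#'
#' Exact per-injection mass balance: after each injection the cell contents
#' are perfectly mixed, the injected volume overflows carrying the
#' post-mixing concentrations (displacement correction), and the bound
#' complex concentration is obtained from the quadratic solution of the
#' 1:1 equilibrium with `n` independent sites per cell molecule. The heat of
#' injection `i` is `dH` times the change in moles of complex in the cell,
#' `q_i = dH * V0 * (B_i - B_{i-1} * V0 / (V0 + dV_i))`.
#'
#' @param K_D Dissociation constant, molar.
#' @param n Stoichiometry (sites per cell molecule).
#' @param dH Enthalpy per mole of complex, kcal/mol.
#' @param cell_conc Cell (macromolecule) concentration, molar.
#' @param syringe_conc Syringe (titrant) concentration, molar.
#' @param cell_volume_ul Cell volume, microlitres.
#' @param injection_volumes_ul Injection volumes, microlitres.
#' @return Numeric vector of heats per injection, microcalories.
#' @export
itc_heats <- function(K_D, n, dH, cell_conc, syringe_conc,
                      cell_volume_ul = 170,
                      injection_volumes_ul = rep(2.43, 20)) {
  stopifnot(K_D > 0, n > 0, cell_conc > 0, syringe_conc > 0,
            cell_volume_ul > 0, all(injection_volumes_ul > 0))
  V0 <- cell_volume_ul * 1e-6           # litres
  M <- cell_conc; X <- 0; B_prev <- 0
  q <- numeric(length(injection_volumes_ul))
  for (i in seq_along(injection_volumes_ul)) {
    dv <- injection_volumes_ul[i] * 1e-6
    d <- V0 / (V0 + dv)
    M <- M * d
    X <- (X * V0 + syringe_conc * dv) / (V0 + dv)
    S <- n * M                          # site concentration
    B <- ((S + X + K_D) - sqrt((S + X + K_D)^2 - 4 * S * X)) / 2
    q[i] <- dH * 1e9 * V0 * (B - B_prev * d)   # kcal/mol * mol -> ucal
    B_prev <- B
  }
  q
}

#' NMR chemical-shift perturbation
#'
#' Combined backbone-amide shift distance
#' `delta = sqrt(ddH^2 + (ddN / 5)^2)` between free and bound assignments.
#' Residues present in only one of the two tables are dropped from the
#' result and reported in the `unmatched` attribute (and a warning), never
#' treated as zero perturbation.
#'
#' @param free,bound Data frames with columns `residue`, `d1H`, `d15N`
#'   (chemical shifts in ppm).
#' @return Tibble with `residue`, `delta_1H`, `delta_15N`, `delta_delta`
#'   for residues assigned in both states; attribute `unmatched` lists the
#'   residues dropped.
#' @export
shift_perturbation <- function(free, bound) {
  for (d in list(free, bound))
    if (!all(c("residue", "d1H", "d15N") %in% names(d)))
      abort("free and bound need columns residue, d1H, d15N")
  common <- intersect(free$residue, bound$residue)
  unmatched <- setdiff(union(free$residue, bound$residue), common)
  if (length(unmatched))
    warn(paste("residues without paired assignment dropped:",
               paste(unmatched, collapse = ", ")))
  f <- free[match(common, free$residue), ]
  b <- bound[match(common, bound$residue), ]
  out <- tibble(residue = common,
                delta_1H = b$d1H - f$d1H,
                delta_15N = b$d15N - f$d15N)
  out$delta_delta <- sqrt(out$delta_1H^2 + (out$delta_15N / 5)^2)
  attr(out, "unmatched") <- unmatched
  out
}
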