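#' Oxygen switch regulating growth
#'
#' Regularized step function of the oxygen mass fraction: 0 at or below the
#' hypoxia threshold, a half-cosine ramp between the thresholds, 1 at or
#' above the optimal mass fraction. Growth and growth-linked oxygen
#' consumption are proportional to it.
#'
#' @param omega_nl Oxygen mass fraction in the interstitial fluid.
#' @param omega_crit Hypoxia threshold (growth stops below it).
#' @param omega_env Optimal oxygen mass fraction.
#' @return Values in \[0, 1\], continuous and non-decreasing in `omega_nl`.
#' @export
growth_switch_H <- function(omega_nl, omega_crit, omega_env) {
  if (!(omega_crit < omega_env))
    stop("omega_crit must be below omega_env", call. = FALSE)
  x <- (omega_nl - omega_crit) / (omega_env - omega_crit)
  x <- pmin(pmax(x, 0), 1)
  0.5 - 0.5 * cos(pi * x)
}

#' Pressure switch inhibiting growth
#'
#' Linear ramp in the tumor-cell pressure: 0 at or below `p1`, 1 at or above
#' `p_crit`. Growth is multiplied by its complement `1 - Hp`.
#'
#' @param p_t Tumor-cell-phase pressure, Pa.
#' @param p1 Pressure at which inhibition starts, Pa.
#' @param p_crit Pressure of full inhibition, Pa.
#' @return Values in \[0, 1\].
#' @export
pressure_switch_Hp <- function(p_t, p1, p_crit) {
  if (!(p1 < p_crit)) stop("p1 must be below p_crit", call. = FALSE)
  pmin(pmax((p_t - p1) / (p_crit - p1), 0), 1)
}

#' Oxygen switch regulating baseline metabolism
#'
#' Variant of the growth switch without a hypoxia cutoff: metabolism decays
#' smoothly all the way to zero oxygen, `0.5 - 0.5 cos(pi w / w_env)` below
#' `omega_env` and 1 above.
#'
#' @inheritParams growth_switch_H
#' @return Values in \[0, 1\], with value 0 at zero oxygen.
#' @export
metabolism_switch_Htilde <- function(omega_nl, omega_env) {
  if (any(omega_nl < 0)) stop("omega_nl must be non-negative", call. = FALSE)
  ifelse(omega_nl >= omega_env, 1,
         0.5 - 0.5 * cos(pi * omega_nl / omega_env))
}

#' Pressure-saturation closure of the tumor-cell phase
#'
#' Saturation of the tumor-cell phase as a function of the cell/IF pressure
#' difference: `S_t = (2/pi) arctan(p_tl / ((1 - omega_Nt) a))`. The
#' necrotic fraction thins the effective resistance, so at a fixed pressure
#' difference a more necrotic tissue packs more cells (higher saturation).
#' Negative pressure differences are clamped to zero saturation: where the
#' cell pressure does not exceed the IF pressure there is no cell phase.
#'
#' @param p_tl Pressure difference `p_t - p_l`, Pa.
#' @param omega_Nt Necrotic mass fraction of the cell phase, in \[0, 1).
#' @param a Saturation parameter, Pa.
#' @return Saturation in \[0, 1).
#' @export
cell_saturation <- function(p_tl, omega_Nt, a) {
  if (any(a <= 0)) stop("'a' must be positive", call. = FALSE)
  if (any(omega_Nt < 0) || any(omega_Nt >= 1))
    stop("omega_Nt must lie in [0, 1)", call. = FALSE)
  (2 / pi) * atan(pmax(p_tl, 0) / ((1 - omega_Nt) * a))
}

#' Interstitial-fluid saturation
#'
#' The two fluid saturations partition the pore space: `S_l = 1 - S_t`.
#'
#' @param S_t Tumor-cell saturation in \[0, 1\].
#' @return `1 - S_t`.
#' @export
liquid_saturation <- function(S_t) {
  stopifnot(all(S_t >= 0), all(S_t <= 1))
  1 - S_t
}

#' Effective oxygen diffusivity in the porous interstitium
#'
#' Fickian diffusivity reduced by the tortuosity of the cell-cell
#' interstitium: `D = D0 (eps S_l)^delta`.
#'
#' @param eps Porosity.
#' @param S_l Interstitial-fluid saturation.
#' @param D0_nl Free diffusivity, m^2/s.
#' @param delta Tortuosity exponent (default 2).
#' @return Diffusivity in m^2/s, between 0 and `D0_nl`.
#' @export
oxygen_diffusivity <- function(eps, S_l, D0_nl, delta = 2) {
  x <- eps * S_l
  if (any(x < 0) || any(x > 1))
    stop("eps * S_l must lie in [0, 1]", call. = FALSE)
  D0_nl * x^delta
}

#' Hydraulic conductivity of a fluid phase
#'
#' Darcy mobility `k k_rel / mu_f` with power-law relative permeability
#' `k_rel = S_f^A`.
#'
#' @param k Intrinsic permeability, m^2.
#' @param S_f Saturation of the fluid phase.
#' @param mu_f Fluid dynamic viscosity, Pa s.
#' @param A Relative-permeability exponent.
#' @return Conductivity `k S_f^A / mu_f`.
#' @export
hydraulic_conductivity <- function(k, S_f, mu_f, A = 2) {
  if (any(mu_f <= 0)) stop("mu_f must be positive", call. = FALSE)
  stopifnot(all(k > 0), all(S_f >= 0), all(S_f <= 1))
  k * S_f^A / mu_f
}

#' Growth mass exchange from interstitial fluid to the tumor-cell phase
#'
#' Product of the growth rate with the oxygen switch, the complement of the
#' pressure switch, and the living cell volume fraction
#' `(1 - omega_Nt) eps S_t`.
#'
#' @param omega_nl Oxygen mass fraction.
#' @param p_t Tumor-cell pressure, Pa.
#' @param omega_Nt Necrotic mass fraction.
#' @param eps Porosity.
#' @param S_t Tumor-cell saturation.
#' @param params A [cell_line_parameters()] object.
#' @return Mass exchange rate, kg/(m^3 s).
#' @export
growth_mass_exchange <- function(omega_nl, p_t, omega_Nt, eps, S_t, params) {
  H <- growth_switch_H(omega_nl, params$omega_crit, params$omega_env)
  Hp <- pressure_switch_Hp(p_t, params$p1, params$p_crit)
  params$gamma_gt * H * (1 - Hp) * (1 - omega_Nt) * eps * S_t
}

#' Oxygen sink due to growth and metabolism
#'
#' Two contributions scaled by the living cell fraction: growth-linked
#' consumption (gated like growth by oxygen and pressure) and baseline
#' metabolic consumption (gated only by the metabolism switch, so it
#' persists when growth is pressure-inhibited).
#'
#' @inheritParams growth_mass_exchange
#' @return Consumption rate, kg/(m^3 s).
#' @export
oxygen_sink <- function(omega_nl, p_t, omega_Nt, eps, S_t, params) {
  H <- growth_switch_H(omega_nl, params$omega_crit, params$omega_env)
  Hp <- pressure_switch_Hp(p_t, params$p1, params$p_crit)
  Ht <- metabolism_switch_Htilde(omega_nl, params$omega_env)
  (params$gamma_gnl * H * (1 - Hp) + params$gamma_0nl * Ht) *
    (1 - omega_Nt) * eps * S_t
}

#' Hypoxic necrosis source of the necrotic cell fraction
#'
#' `gamma_Nt (1 - Htilde) (1 - omega_Nt) eps S_t`: zero at full oxygenation,
#' maximal at zero oxygen, and proportional to the living cell fraction.
#'
#' @inheritParams growth_mass_exchange
#' @param gamma_Nt Necrosis rate, kg/(m^3 s).
#' @param omega_env Optimal oxygen mass fraction.
#' @return Necrosis source term, kg/(m^3 s).
#' @export
necrosis_rate <- function(omega_nl, omega_Nt, eps, S_t, gamma_Nt, omega_env) {
  Ht <- metabolism_switch_Htilde(omega_nl, omega_env)
  gamma_Nt * (1 - Ht) * (1 - omega_Nt) * eps * S_t
}

#' Growing (proliferative) cell fraction observable
#'
#' Comparison quantity mirroring experimental proliferative-cell staining:
#' zero under hypoxia, otherwise `S_t omega_nl / omega_env`.
#'
#' @inheritParams growth_mass_exchange
#' @return Dimensionless proliferative fraction.
#' @export
growing_fraction <- function(omega_nl, S_t, params) {
  ifelse(omega_nl <= params$omega_crit, 0,
         S_t * omega_nl / params$omega_env)
}

#' Lame constants from engineering moduli
#'
#' @param E Young modulus, Pa.
#' @param nu Poisson ratio (must be below 0.5).
#' @return List with `lambda` and `mu`, Pa.
#' @export
lame_constants <- function(E, nu) {
  if (any(nu >= 0.5))
    stop("nu = 0.5 (incompressible) is not representable", call. = FALSE)
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

#' Linear-elastic effective stress of the scaffold
#'
#' `sigma = lambda tr(eps) I + 2 mu eps` applied to a small-strain symmetric
#' tensor given as a 3x3 matrix (or the Voigt law applied componentwise).
#'
#' @param strain 3x3 symmetric small-strain tensor.
#' @param E Young modulus, Pa.
#' @param nu Poisson ratio.
#' @return 3x3 stress tensor, Pa.
#' @export
effective_stress <- function(strain, E, nu) {
  stopifnot(is.matrix(strain), nrow(strain) == 3, ncol(strain) == 3)
  if (max(abs(strain - t(strain))) > 1e-12 * max(1, max(abs(strain))))
    stop("strain tensor must be symmetric", call. = FALSE)
  lm <- lame_constants(E, nu)
  lm$lambda * sum(diag(strain)) * diag(3) + 2 * lm$mu * strain
}

#' Solid pressure acting on the scaffold
#'
#' Saturation-weighted fluid pressure `p_s = S_t p_t + (1 - S_t) p_l`, the
#' pressure entering the Biot effective-stress split.
#'
#' @param S_t Tumor-cell saturation.
#' @param p_t Tumor-cell pressure, Pa.
#' @param p_l Interstitial-fluid pressure, Pa.
#' @return Solid pressure, Pa.
#' @export
solid_pressure <- function(S_t, p_t, p_l) {
  stopifnot(all(S_t >= 0), all(S_t <= 1))
  S_t * p_t + (1 - S_t) * p_l
}

#' Porosity update from the deformation Jacobian
#'
#' With an incompressible scaffold the solid volume fraction obeys
#' `(1 - eps) J = (1 - eps0)`, so `eps = 1 - (1 - eps0) / J`.
#'
#' @param eps0 Reference porosity.
#' @param J Deformation Jacobian (volume ratio), positive.
#' @return Updated porosity.
#' @export
update_porosity <- function(eps0, J) {
  stopifnot(all(J > 0))
  eps <- 1 - (1 - eps0) / J
  if (any(eps <= 0))
    stop("porosity collapse: J too small for the given reference porosity",
         call. = FALSE)
  eps
}
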