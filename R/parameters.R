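#' Cell-line parameters of the multiphase growth model
#'
#' Bundles the cell-line-specific rate constants and thresholds that drive
#' growth, oxygen consumption and hypoxic necrosis of the tumor-cell (TC)
#' phase, together with the pressure-saturation parameter `a` and the TC
#' dynamic viscosity.
#'
#' @param gamma_gt TC growth rate, kg/(m^3 s).
#' @param gamma_gnl Growth-linked oxygen consumption rate, kg/(m^3 s).
#' @param gamma_0nl Metabolic oxygen consumption rate, kg/(m^3 s).
#' @param gamma_Nt Hypoxic necrosis rate, kg/(m^3 s): like the other rate
#'   constants it is a mass rate; divided by the cell density it gives the
#'   fractional necrosis rate per unit living mass (1e-5 1/s at the default,
#'   i.e. a time scale of about a day under full hypoxia).
#' @param omega_crit Hypoxia threshold oxygen mass fraction (dimensionless);
#'   below it growth stops and necrosis proceeds.
#' @param omega_env Optimal oxygen mass fraction (dimensionless); the value
#'   4.2e-6 corresponds via Henry's law to about 90 mmHg.
#' @param p1 TC pressure at which growth inhibition starts, Pa.
#' @param p_crit TC pressure at which growth is fully inhibited, Pa.
#' @param a Pressure-saturation parameter combining extracellular-matrix
#'   network thinness and cell surface tension, Pa.
#' @param mu_t Dynamic viscosity of the TC phase, Pa s.
#'
#' @return An object of class `cell_line_parameters` (a validated named list).
#' @seealso [cell_line_preset()] for the generic and CT26-optimized sets.
#' @export
cell_line_parameters <- function(gamma_gt = 4e-2,
                                 gamma_gnl = 4e-4,
                                 gamma_0nl = 6e-4,
                                 gamma_Nt = 0.01,
                                 omega_crit = 1e-6,
                                 omega_env = 4.2e-6,
                                 p1 = 1800,
                                 p_crit = 4000,
                                 a = 800,
                                 mu_t = 36) {
  p <- list(gamma_gt = gamma_gt, gamma_gnl = gamma_gnl,
            gamma_0nl = gamma_0nl, gamma_Nt = gamma_Nt,
            omega_crit = omega_crit, omega_env = omega_env,
            p1 = p1, p_crit = p_crit, a = a, mu_t = mu_t)
  validate_cell_line_parameters(p)
  class(p) <- c("cell_line_parameters", "list")
  p
}

validate_cell_line_parameters <- function(p) {
  stopifnot(is.numeric(unlist(p)), all(is.finite(unlist(p))))
  if (p$gamma_gt < 0 || p$gamma_gnl < 0 || p$gamma_0nl < 0 || p$gamma_Nt < 0)
    stop("all rate parameters must be non-negative", call. = FALSE)
  if (!(p$omega_crit > 0 && p$omega_crit < p$omega_env && p$omega_env < 1))
    stop("oxygen thresholds must satisfy 0 < omega_crit < omega_env < 1",
         call. = FALSE)
  if (!(p$p1 > 0 && p$p1 < p$p_crit))
    stop("pressure thresholds must satisfy 0 < p1 < p_crit", call. = FALSE)
  if (p$a <= 0) stop("saturation parameter 'a' must be positive", call. = FALSE)
  if (p$mu_t <= 0) stop("mu_t must be positive", call. = FALSE)
  invisible(p)
}

#' Named cell-line parameter presets
#'
#' Two presets are shipped for the CT26 mouse colon carcinoma line:
#' `"generic"`, the literature-averaged initial-guess values, and
#' `"CT26-optimized"`, the values identified on free-growth and
#' encapsulated training data (growth rate 3.33e-2 kg/(m^3 s), metabolic
#' oxygen consumption 6.65e-4 kg/(m^3 s), a = 890 Pa, p1 = 1432 Pa,
#' p_crit = 5944 Pa). Parameters reported as non-identifiable from the data
#' (mu_t, gamma_gnl) keep their generic values.
#'
#' @param name Preset name, `"generic"` or `"CT26-optimized"`.
#' @return A [cell_line_parameters()] object.
#' @export
cell_line_preset <- function(name = c("generic", "CT26-optimized")) {
  name <- match.arg(name)
  switch(name,
    "generic" = cell_line_parameters(),
    "CT26-optimized" = cell_line_parameters(
      gamma_gt = 3.33e-2, gamma_gnl = 4e-4, gamma_0nl = 6.65e-4,
      p1 = 1432, p_crit = 5944, a = 890))
}

#' Phase-level transport and fluid properties
#'
#' Properties shared by the three phases: constant densities (all phases are
#' incompressible, so the Biot coefficient is 1), interstitial-fluid
#' viscosity, free oxygen diffusivity with its tortuosity exponent, and the
#' relative-permeability exponents of the two fluid phases.
#'
#' Defaults not identifiable from capsule data are set from tumor
#' interstitium literature: with intrinsic permeability 1.8e-15 m^2 the
#' default `mu_l` = 0.01 Pa s gives a Darcy mobility k/mu_l of 1.8e-13
#' m^2/(Pa s), at the permeable end of the measured range for tumor
#' interstitium; it reproduces interstitial-fluid pressure excursions of a
#' few Pa in encapsulated growth.
#'
#' @param rho_s,rho_t,rho_l Phase densities, kg/m^3.
#' @param mu_l Interstitial-fluid dynamic viscosity, Pa s.
#' @param D0_nl Free oxygen diffusivity in the interstitial fluid, m^2/s.
#' @param delta Tortuosity exponent of the oxygen diffusivity closure
#'   (default 2).
#' @param A_t,A_l Relative-permeability exponents of the TC and IF phases.
#' @return An object of class `phase_properties`.
#' @export
phase_properties <- function(rho_s = 1000, rho_t = 1000, rho_l = 1000,
                             mu_l = 0.01, D0_nl = 3.2e-9, delta = 2,
                             A_t = 2, A_l = 2) {
  p <- list(rho_s = rho_s, rho_t = rho_t, rho_l = rho_l, mu_l = mu_l,
            D0_nl = D0_nl, delta = delta, A_t = A_t, A_l = A_l)
  stopifnot(p$rho_s > 0, p$rho_t > 0, p$rho_l > 0, p$mu_l > 0,
            p$D0_nl > 0, p$delta >= 0, p$A_t >= 0, p$A_l >= 0)
  class(p) <- c("phase_properties", "list")
  p
}

#' Poroelastic material of one spatial subdomain
#'
#' @param E Young modulus of the solid scaffold, Pa.
#' @param nu Poisson ratio (strictly below the incompressible limit 0.5).
#' @param k Intrinsic permeability, m^2.
#' @param eps0 Reference porosity (volume not occupied by the scaffold).
#' @param k_t_factor Multiplier on the intrinsic permeability seen by the
#'   tumor-cell phase only; the alginate shell uses a strong reduction
#'   (default 1) as the penalty that keeps cells out of the gel.
#' @param a_factor Multiplier on the pressure-saturation parameter `a` in
#'   this subdomain (default 1). The alginate gel, whose ~20 nm pores
#'   cannot host cells, uses a very large factor: at any physiological
#'   cell/IF pressure difference its cell saturation stays negligible,
#'   which (together with `k_t_factor`) confines the cell phase to the
#'   capsule lumen.
#' @return An object of class `subdomain_material`.
#' @export
subdomain_material <- function(E, nu = 0.4, k = 1.8e-15, eps0 = 0.8,
                               k_t_factor = 1, a_factor = 1) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, k > 0, eps0 > 0, eps0 < 1,
            k_t_factor > 0, a_factor >= 1)
  m <- list(E = E, nu = nu, k = k, eps0 = eps0, k_t_factor = k_t_factor,
            a_factor = a_factor)
  class(m) <- c("subdomain_material", "list")
  m
}

#' Default materials for the three concentric subdomains
#'
#' MCTS interior: extracellular-matrix scaffold, E = 1 kPa. Alginate shell:
#' E = 68 kPa with the tumor-cell permeability reduced by six orders of
#' magnitude (infiltration penalty). Exterior: fictitious scaffold
#' E = 0.6 kPa, porosity 0.99, mechanically negligible but required by the
#' porous-media framework.
#'
#' @param E_alg Alginate Young modulus, Pa (measured 68 +/- 21 kPa).
#' @return Named list of [subdomain_material()] for `mcts`, `alginate`,
#'   `exterior`.
#' @export
default_materials <- function(E_alg = 68e3) {
  list(
    mcts = subdomain_material(E = 1e3, nu = 0.4, k = 1.8e-15, eps0 = 0.8),
    alginate = subdomain_material(E = E_alg, nu = 0.4, k = 1.8e-15,
                                  eps0 = 0.8, k_t_factor = 1e-6,
                                  a_factor = 1e6),
    exterior = subdomain_material(E = 0.6e3, nu = 0.4, k = 1.8e-15,
                                  eps0 = 0.99))
}

#' Full model parameter bundle
#'
#' @param cell_line A [cell_line_parameters()] object or preset name.
#' @param phases A [phase_properties()] object.
#' @return Object of class `model_parameters`.
#' @export
model_parameters <- function(cell_line = "generic",
                             phases = phase_properties()) {
  if (is.character(cell_line)) cell_line <- cell_line_preset(cell_line)
  validate_cell_line_parameters(cell_line)
  stopifnot(inherits(phases, "phase_properties"))
  structure(list(cell_line = cell_line, phases = phases),
            class = c("model_parameters", "list"))
}

#' Read or write a model configuration as YAML/JSON
#'
#' Flat key-value serialization with one section per parameter group, so a
#' run is fully described by a single text file.
#'
#' @param params A [model_parameters()] object.
#' @param path File path; extension `.json` selects JSON, anything else YAML.
#' @return `read_model_config` returns a [model_parameters()] object.
#' @export
write_model_config <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  x <- list(cell_line = unclass(params$cell_line),
            phases = unclass(params$phases))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cl <- do.call(cell_line_parameters, x$cell_line)
  ph <- do.call(phase_properties, x$phases)
  model_parameters(cell_line = cl, phases = ph)
}
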