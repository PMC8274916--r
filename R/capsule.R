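#' Capsule geometry for the dynamometer inverse analysis
#'
#' @param R_in0 Initial inner radius, m.
#' @param R_out0 Initial outer radius, m (alternatively give `h`).
#' @param E_alg Alginate Young modulus, Pa (measured 68 +/- 21 kPa).
#' @param h Shell thickness, m; used when `R_out0` is missing.
#' @return Object of class `capsule_geometry`.
#' @export
capsule_geometry <- function(R_in0, R_out0 = NULL, E_alg = 68e3, h = NULL) {
  if (is.null(R_out0)) {
    if (is.null(h)) stop("give either R_out0 or h", call. = FALSE)
    R_out0 <- R_in0 + h
  }
  if (!(R_out0 > R_in0 && R_in0 > 0))
    stop("invalid geometry: need R_out0 > R_in0 > 0", call. = FALSE)
  stopifnot(E_alg > 0)
  structure(list(R_in0 = R_in0, R_out0 = R_out0, E_alg = E_alg),
            class = c("capsule_geometry", "list"))
}

#' Confinement pressure from inner-wall displacement
#'
#' Inverts the thick-walled incompressible spherical shell relation
#' `u(R_in) = (3/4) (P/E) R_in / (1 - (R_in/R_out)^3)` to turn a measured
#' inner-wall dilation into the internal pressure acting on the capsule:
#' `P = (4/3) E (1 - (R_in/R_out)^3) u / R_in`.
#'
#' @param u Radial displacement of the inner wall, m (non-negative).
#' @param geometry A [capsule_geometry()].
#' @return Confinement pressure, Pa.
#' @export
confinement_pressure_from_u <- function(u, geometry) {
  stopifnot(inherits(geometry, "capsule_geometry"))
  if (any(u < 0)) stop("u must be non-negative", call. = FALSE)
  g <- geometry
  (4 / 3) * g$E_alg * (1 - (g$R_in0 / g$R_out0)^3) * u / g$R_in0
}

#' Confinement pressure time series from the inner-radius track
#'
#' Uses shell volume conservation `R_out^3 - R_in^3 = const` to eliminate
#' the outer radius, so the pressure is a function of `R_in(t)` only:
#' `P(t) = (4/3) E [1 - 1 / (1 + d(R0^3)/R_in^3)] u(R_in) / R_in`
#' with `d(R0^3) = R_out0^3 - R_in0^3` and `u = R_in(t) - R_in0`.
#'
#' @param R_in Vector of inner radii over time, m.
#' @param geometry A [capsule_geometry()].
#' @param R_out Optional matching outer radii; if supplied, shell volume
#'   conservation is checked and a warning raised when violated beyond 1%.
#' @return Vector of confinement pressures, Pa.
#' @export
confinement_pressure_timeseries <- function(R_in, geometry, R_out = NULL) {
  stopifnot(inherits(geometry, "capsule_geometry"))
  g <- geometry
  if (any(R_in < g$R_in0 - 1e-12 * g$R_in0))
    warning("shell track shrinks below its initial inner radius")
  if (!is.null(R_out)) {
    dV0 <- g$R_out0^3 - g$R_in0^3
    dV <- R_out^3 - R_in^3
    if (any(abs(dV - dV0) > 0.01 * dV0))
      warning("shell volume conservation violated by more than 1%")
  }
  u <- pmax(R_in - g$R_in0, 0)
  dR03 <- g$R_out0^3 - g$R_in0^3
  (4 / 3) * g$E_alg * (1 - 1 / (1 + dR03 / R_in^3)) * u / R_in
}

#' Solid-pressure estimate from the confinement pressure
#'
#' Corrects the inverse-analysis confinement pressure for the elastic
#' compression of the extracellular-matrix scaffold:
#' `p_s = P_conf + 3 K_T u / R_in`, with `K_T` the scaffold bulk modulus.
#'
#' @param P_conf Confinement pressure, Pa.
#' @param u Inner-wall displacement, m.
#' @param R_in Inner radius, m.
#' @param K_T Bulk modulus of the scaffold, Pa (non-negative).
#' @return Estimated solid pressure, Pa.
#' @export
solid_pressure_estimate <- function(P_conf, u, R_in, K_T) {
  if (any(K_T < 0)) stop("K_T must be non-negative", call. = FALSE)
  P_conf + 3 * K_T * u / R_in
}

#' Compare simulated wall pressures with the dynamometer inverse analysis
#'
#' Applies the shell inverse analysis to the simulation's own inner-radius
#' track and tabulates it against the model's inner-wall solid pressure,
#' tumor-cell pressure and radial effective stress, mirroring the published
#' comparison of experimental and numerical stresses.
#'
#' @param sim_result A `simulation_result` from [run_simulation()] of an
#'   encapsulated configuration.
#' @param geometry A [capsule_geometry()] matching the simulated capsule.
#' @param K_T Scaffold bulk modulus used in the solid-pressure estimate, Pa
#'   (default from E = 1 kPa, nu = 0.4).
#' @return A data.frame with columns `time_s`, `P_conf_inverse`,
#'   `p_s_estimate`, `p_s_model`, `p_t_model`, `sigma_rr_model`.
#' @export
compare_pressures <- function(sim_result, geometry,
                              K_T = 1e3 / (3 * (1 - 2 * 0.4))) {
  stopifnot(inherits(sim_result, "simulation_result"))
  if (!isTRUE(sim_result$encapsulated))
    stop("no capsule in this simulation: run an encapsulated configuration",
         call. = FALSE)
  ts <- sim_result$series
  P_inv <- confinement_pressure_timeseries(ts$R_in_m, geometry)
  u <- pmax(ts$R_in_m - geometry$R_in0, 0)
  data.frame(
    time_s = ts$time_s,
    P_conf_inverse = P_inv,
    p_s_estimate = solid_pressure_estimate(P_inv, u, ts$R_in_m, K_T),
    p_s_model = ts$p_s_wall_Pa,
    p_t_model = ts$p_t_wall_Pa,
    sigma_rr_model = ts$sigma_rr_wall_Pa)
}
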