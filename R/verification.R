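#' Relative root-mean-square error
#'
#' `sqrt( (1/n) sum( ((ex - num)/ex)^2 ) )`: the error of a numerical series
#' relative to a reference, evaluated pointwise.
#'
#' @param xi_num Numerical values.
#' @param xi_ex Reference values (all nonzero).
#' @return Dimensionless RMSE.
#' @export
rmse <- function(xi_num, xi_ex) {
  if (length(xi_num) != length(xi_ex))
    stop("inputs must have equal length", call. = FALSE)
  if (any(xi_ex == 0))
    stop("reference contains zero entries; relative error undefined",
         call. = FALSE)
  sqrt(mean(((xi_ex - xi_num) / xi_ex)^2))
}

#' Configuration of the Terzaghi consolidation benchmark
#'
#' One-dimensional poroelastic column of length `L` under a constant
#' compressive surface load applied at the drained face.
#'
#' @param L Column length, m (default 100 um).
#' @param p0 Applied load, Pa.
#' @param E,nu Drained elastic constants of the scaffold.
#' @param k Intrinsic permeability, m^2.
#' @param mu_l Fluid viscosity, Pa s.
#' @param eps0 Porosity.
#' @param series_terms Truncation of the analytical series.
#' @return Object of class `terzaghi_config`. The consolidation coefficient
#'   `c_v = k (lambda + 2 mu) / mu_l` is precomputed.
#' @export
terzaghi_config <- function(L = 100e-6, p0 = 1e3, E = 100e3, nu = 0.3,
                            k = 1.8e-15, mu_l = 0.1, eps0 = 0.8,
                            series_terms = 200) {
  stopifnot(L > 0, p0 > 0, E > 0, nu >= 0, nu < 0.5, k > 0, mu_l > 0,
            series_terms >= 1)
  lm <- lame_constants(E, nu)
  structure(list(L = L, p0 = p0, E = E, nu = nu, k = k, mu_l = mu_l,
                 eps0 = eps0, series_terms = as.integer(series_terms),
                 c_v = k * (lm$lambda + 2 * lm$mu) / mu_l),
            class = c("terzaghi_config", "list"))
}

#' Analytical Terzaghi pore-pressure solution
#'
#' Truncated cosine-exponential series for the pore pressure in a column
#' drained and loaded at `y = L`:
#' `p(y, t) = p0 (4/pi) sum_k (-1)^(k-1)/(2k-1) cos((2k-1) (pi/2) y/L)
#'  exp(-(2k-1)^2 (pi^2/4) t_bar)` with `t_bar = c_v t / L^2`.
#'
#' @param y Positions in `[0, L]`, m.
#' @param t_bar Dimensionless consolidation time (positive).
#' @param config A [terzaghi_config()].
#' @param tol Relative truncation tolerance on the series tail.
#' @return Pore pressure, Pa.
#' @export
terzaghi_analytic <- function(y, t_bar, config, tol = 1e-8) {
  stopifnot(inherits(config, "terzaghi_config"))
  if (any(y < 0) || any(y > config$L))
    stop("y must lie in [0, L]", call. = FALSE)
  if (t_bar <= 0) stop("t_bar must be positive", call. = FALSE)
  K <- config$series_terms
  kk <- 2 * seq_len(K) - 1
  tail_bound <- (4 / pi) / kk[K] * exp(-kk[K]^2 * pi^2 / 4 * t_bar)
  if (tail_bound > tol)
    stop("series not converged at the requested tolerance; ",
         "increase series_terms", call. = FALSE)
  ek <- exp(-kk^2 * pi^2 / 4 * t_bar) * (-1)^(seq_len(K) - 1) / kk
  cosm <- cos(outer(y / config$L, kk) * (pi / 2))
  config$p0 * (4 / pi) * as.vector(cosm %*% ek)
}

# Build the Cartesian single-fluid column state for the benchmark.
.terzaghi_setup <- function(config, dh) {
  m <- subdomain_material(E = config$E, nu = config$nu, k = config$k,
                          eps0 = config$eps0)
  domain <- domain_spec(R_seed = config$L / 2, R_domain = config$L,
                        materials = list(mcts = m, exterior = m),
                        encapsulated = FALSE)
  params <- model_parameters(
    cell_line = cell_line_parameters(gamma_gt = 0, gamma_gnl = 0,
                                     gamma_0nl = 0, gamma_Nt = 0),
    phases = phase_properties(mu_l = config$mu_l))
  list(domain = domain, params = params, material = m)
}

#' Run the Terzaghi consolidation verification
#'
#' Runs the solver kernel in its single-fluid, no-growth Cartesian variant
#' (cell-pressure and oxygen fields frozen, small-strain) under a constant
#' drained surface load, compares the pore-pressure profiles with
#' [terzaghi_analytic()] at the requested dimensionless times, and sums the
#' relative RMSE values.
#'
#' @param config A [terzaghi_config()].
#' @param dh Element size, m.
#' @param dt_bar Dimensionless time step.
#' @param t_bars Dimensionless comparison times.
#' @return List with `sum_rmse`, `per_time_rmse`, and a `table` of
#'   `(t_bar, y, p_analytic, p_numeric)` at the interior nodes.
#' @export
run_terzaghi_verification <- function(config = terzaghi_config(),
                                      dh = 5e-6, dt_bar = 1e-4,
                                      t_bars = c(0.01, 0.1, 0.5, 1)) {
  stopifnot(inherits(config, "terzaghi_config"))
  su <- .terzaghi_setup(config, dh)
  dt <- dt_bar * config$L^2 / config$c_v
  disc <- discretization(dh = dh, dt = dt, t_end = max(t_bars) * config$L^2 /
                           config$c_v, geometry = "cartesian",
                         small_strain = TRUE, newton_tol = 1e-9)
  st <- initialize_state(su$domain, disc, su$params)
  ns <- st$mesh$ns
  st$ptl[] <- 0
  st$St_q[] <- 0
  st$pl <- rep(config$p0, ns)
  st$pl[ns] <- 0
  st$eSlom_q <- st$eps_q * su$params$cell_line$omega_env
  cache <- new.env(parent = emptyenv())
  nsteps <- round(max(t_bars) / dt_bar)
  target_steps <- round(t_bars / dt_bar)
  tabs <- list()
  per <- numeric(0)
  y <- st$mesh$nodes
  interior <- seq_len(ns - 1L)   # drained node excluded (reference is 0)
  for (n in seq_len(nsteps)) {
    st <- advance_step(st, disc, su$params, active_ptl = FALSE,
                       active_om = FALSE, traction = config$p0,
                       cache = cache)
    hit <- which(target_steps == n)
    if (length(hit)) {
      tb <- t_bars[hit[1]]
      pex <- terzaghi_analytic(y[interior], tb, config)
      pnum <- st$pl[interior]
      per[sprintf("t_bar=%g", tb)] <- rmse(pnum, pex)
      tabs[[length(tabs) + 1L]] <- data.frame(
        t_bar = tb, y = y[interior], p_analytic = pex, p_numeric = pnum)
    }
  }
  list(sum_rmse = sum(per), per_time_rmse = per,
       table = do.call(rbind, tabs))
}

#' Mesh-refinement study on the free-growth configuration
#'
#' Runs the free-growth simulation at each element size, monitors the
#' oxygen mass fraction at the spheroid center over the whole horizon, and
#' reports the relative RMSE of each run against the finest-mesh reference.
#'
#' @param dh_list Element sizes, m (must contain `reference_dh`).
#' @param reference_dh Element size of the reference run, m.
#' @param domain A free-growth [domain_spec()].
#' @param disc A [discretization()] template (its `dh` is overridden).
#' @param params A [model_parameters()].
#' @return data.frame with columns `dh_m` and `rmse` (reference row 0), with
#'   the center-oxygen series of each run in attribute `"series"`.
#' @export
mesh_convergence_study <- function(dh_list, reference_dh, domain, disc,
                                   params) {
  if (length(dh_list) < 2L)
    stop("need at least two mesh sizes", call. = FALSE)
  if (!any(abs(dh_list - reference_dh) < 1e-15))
    stop("reference_dh must be among dh_list", call. = FALSE)
  runs <- lapply(dh_list, function(dh) {
    d2 <- disc
    d2$dh <- dh
    run_simulation(domain, d2, params)$series
  })
  iref <- which.min(abs(dh_list - reference_dh))
  ref <- runs[[iref]]
  out <- data.frame(dh_m = dh_list, rmse = vapply(runs, function(s) {
    # align on the reference save times (identical dt grids)
    n <- min(nrow(s), nrow(ref))
    rmse(s$omega_center[seq_len(n)][-1], ref$omega_center[seq_len(n)][-1])
  }, numeric(1)))
  attr(out, "series") <- runs
  out
}
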