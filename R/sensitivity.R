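# Cost functions, local response-surface Sobol sensitivity and bounded
# Nelder-Mead calibration. The sensitivity procedure is the LOCAL
# one-at-a-time / pairwise perturbation design with a polynomial response
# surface, not Saltelli-type global sampling; classes are named accordingly.

#' Free-growth cost function
#'
#' Sum of squared mismatches between experimental aggregate volumes and the
#' simulated tumor volume (the full-sphere integral of the cell volume
#' fraction) at the data times.
#'
#' @param sim_result A `simulation_result` of a free-growth run.
#' @param data data.frame (or `experiment_series`) with columns `time_s`,
#'   `volume_m3`.
#' @return Cost value, m^6.
#' @export
cost_free <- function(sim_result, data) {
  stopifnot(inherits(sim_result, "simulation_result"))
  if (inherits(data, "experiment_series"))
    data <- data.frame(time_s = data$times_s, volume_m3 = data$values)
  if (nrow(data) < 1L) stop("empty data", call. = FALSE)
  s <- sim_result$series
  if (max(data$time_s) > max(s$time_s) + 1e-6)
    stop("simulation horizon shorter than the data", call. = FALSE)
  Vs <- stats::approx(s$time_s, s$V_tumor_m3, xout = data$time_s)$y
  sum((data$volume_m3 - Vs)^2)
}

#' Confined-growth cost function
#'
#' Compares two experimental quantities one day after confluence: the
#' inner-wall displacement and the confinement pressure inferred from it,
#' against the model inner-wall displacement and solid pressure. Both terms
#' are boundary averages (the inner wall is a single sphere in radial
#' symmetry); the displacement mismatch enters as an absolute value by
#' default (`dialect = "abs"`) or squared (`dialect = "squared"`).
#'
#' @param sim_result A `simulation_result` of an encapsulated run.
#' @param data List or data.frame with `u_Rin_m` (inner-wall displacement,
#'   m) and `P_conf_Pa` (confinement pressure, Pa), both taken one day
#'   after confluence; optional `t_offset_s` (possibly a vector, matching
#'   `u_Rin_m`/`P_conf_Pa`) overrides the offsets, in which case the cost
#'   sums the per-time terms. A single time point constrains only one
#'   combination of the pressure thresholds (displacement and confinement
#'   pressure are tied through the shell elasticity), so identification
#'   uses a short post-confluence series.
#' @param dialect Form of the displacement term.
#' @return Cost value.
#' @export
cost_conf <- function(sim_result, data, dialect = c("abs", "squared")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(sim_result, "simulation_result"))
  if (!isTRUE(sim_result$encapsulated))
    stop("cost_conf needs an encapsulated simulation", call. = FALSE)
  tc <- sim_result$confluence_time_s
  if (is.na(tc)) stop("confluence not reached in the simulation",
                      call. = FALSE)
  off <- if (!is.null(data$t_offset_s)) data$t_offset_s else 86400
  stopifnot(length(data$u_Rin_m) == length(off),
            length(data$P_conf_Pa) == length(off))
  tstar <- tc + off
  s <- sim_result$series
  if (max(tstar) > max(s$time_s) + 1e-6)
    stop("simulation too short: needs confluence + ", max(off), " s",
         call. = FALSE)
  Rin0 <- sim_result$domain$R_in
  u_sim <- stats::approx(s$time_s, s$R_in_m, xout = tstar)$y - Rin0
  ps_sim <- stats::approx(s$time_s, s$p_s_wall_Pa, xout = tstar)$y
  du <- data$u_Rin_m - u_sim
  term_u <- if (dialect == "abs") abs(du) else du^2
  mean(term_u) + mean((data$P_conf_Pa - ps_sim)^2)
}

#' One-at-a-time perturbation design
#'
#' Perturbs each parameter in turn over the relative grid
#' `[-10, -5, -2, -1, +1, +2, +5, +10]%` and evaluates the cost, recording
#' the relative cost variation `Var = (J - J0)/J0`.
#'
#' @param cost_fn Function taking a named numeric vector of parameter values
#'   and returning the scalar cost.
#' @param base Named numeric vector of baseline parameter values.
#' @param grid Relative perturbations (fractions).
#' @return Object of class `sensitivity_design`: data.frame `runs` with
#'   columns `param`, `frac`, `J`, `Var`, plus the baseline cost `J0`.
#'   Failed runs are kept as `NA` with a warning.
#' @export
first_order_design <- function(cost_fn, base,
                               grid = c(-10, -5, -2, -1, 1, 2, 5, 10) / 100) {
  stopifnot(!is.null(names(base)), all(nzchar(names(base))))
  J0 <- cost_fn(base)
  if (!is.finite(J0) || J0 <= 0)
    stop("baseline cost must be finite and positive", call. = FALSE)
  runs <- expand.grid(param = names(base), frac = grid,
                      stringsAsFactors = FALSE)
  runs$J <- vapply(seq_len(nrow(runs)), function(i) {
    p <- base
    p[runs$param[i]] <- p[runs$param[i]] * (1 + runs$frac[i])
    tryCatch(cost_fn(p), error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(runs$J)) warning("some perturbed runs failed and were excluded")
  runs$Var <- (runs$J - J0) / J0
  structure(list(runs = runs, J0 = J0, base = base, grid = grid,
                 kind = "first_order"),
            class = c("sensitivity_design", "list"))
}

#' Pairwise-interaction perturbation design
#'
#' Evaluates every parameter pair at the two extreme diagonal points of the
#' grid (both at -10% and both at +10%), to be fitted jointly with the
#' one-at-a-time runs by a second-order polynomial response surface.
#'
#' @param cost_fn,base As in [first_order_design()].
#' @param first A `sensitivity_design` from [first_order_design()] for the
#'   same baseline (computed if missing).
#' @param extreme Relative amplitude of the diagonal points.
#' @return Object of class `sensitivity_design` with `kind = "interaction"`,
#'   carrying both run sets.
#' @export
interaction_design <- function(cost_fn, base, first = NULL, extreme = 0.1) {
  if (is.null(first)) first <- first_order_design(cost_fn, base)
  pn <- names(base)
  pairs <- utils::combn(pn, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    for (s in c(-1, 1)) {
      p <- base
      p[pairs[1, j]] <- p[pairs[1, j]] * (1 + s * extreme)
      p[pairs[2, j]] <- p[pairs[2, j]] * (1 + s * extreme)
      J <- tryCatch(cost_fn(p), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        param_i = pairs[1, j], param_j = pairs[2, j], sign = s, J = J)
    }
  }
  pair_runs <- do.call(rbind, rows)
  if (anyNA(pair_runs$J)) warning("some pair runs failed and were excluded")
  pair_runs$Var <- (pair_runs$J - first$J0) / first$J0
  structure(list(runs = first$runs, pair_runs = pair_runs, J0 = first$J0,
                 base = base, grid = first$grid, extreme = extreme,
                 kind = "interaction"),
            class = c("sensitivity_design", "list"))
}

#' First-order Sobol indices from a local response surface
#'
#' Fits the linear response surface `Var = c + sum_i theta_i alpha_i` by
#' least squares on the one-at-a-time runs (`alpha` is each perturbation
#' rescaled to `[-1, 1]`) and normalizes the squared slopes:
#' `S_i = theta_i^2 / sum theta^2`.
#'
#' @param design A `sensitivity_design` from [first_order_design()].
#' @return Object of class `local_sobol_result` with `theta` and `S`.
#' @export
fit_first_order <- function(design) {
  stopifnot(inherits(design, "sensitivity_design"))
  runs <- design$runs[is.finite(design$runs$J), ]
  pn <- names(design$base)
  amax <- max(abs(design$grid))
  X <- sapply(pn, function(p) ifelse(runs$param == p, runs$frac / amax, 0))
  fit <- stats::lm.fit(cbind(1, X), runs$Var)
  theta <- fit$coefficients[-1]
  names(theta) <- pn
  if (all(abs(theta) < 1e-300))
    stop("all slopes are zero; Sobol indices undefined", call. = FALSE)
  structure(list(theta = theta, S = theta^2 / sum(theta^2),
                 theta_pair = NULL, S_pair = NULL, design = design),
            class = c("local_sobol_result", "list"))
}

#' First-order and pairwise Sobol indices from the quadratic surface
#'
#' Fits `Var = c + sum_i theta_i alpha_i + sum_{i>j} theta_ij alpha_i
#' alpha_j` on the combined one-at-a-time and diagonal pair runs, and
#' normalizes all squared coefficients together, so the first-order and
#' pairwise indices sum to one.
#'
#' @param design A `sensitivity_design` from [interaction_design()].
#' @return Object of class `local_sobol_result` with `theta`, `theta_pair`,
#'   `S`, `S_pair`.
#' @export
fit_interaction <- function(design) {
  stopifnot(inherits(design, "sensitivity_design"),
            design$kind == "interaction")
  pn <- names(design$base)
  amax <- max(abs(design$grid))
  r1 <- design$runs[is.finite(design$runs$J), ]
  A1 <- sapply(pn, function(p) ifelse(r1$param == p, r1$frac / amax, 0))
  r2 <- design$pair_runs[is.finite(design$pair_runs$J), ]
  a2 <- design$extreme / amax
  A2 <- sapply(pn, function(p)
    (as.numeric(r2$param_i == p) + as.numeric(r2$param_j == p)) *
      r2$sign * a2)
  pairs <- utils::combn(pn, 2)
  pname <- paste(pairs[1, ], pairs[2, ], sep = ":")
  P1 <- matrix(0, nrow(r1), ncol(pairs), dimnames = list(NULL, pname))
  P2 <- sapply(seq_len(ncol(pairs)), function(j)
    ifelse(r2$param_i == pairs[1, j] & r2$param_j == pairs[2, j], a2^2, 0))
  colnames(P2) <- pname
  X <- rbind(cbind(1, A1, P1), cbind(1, A2, P2))
  yy <- c(r1$Var, r2$Var)
  fit <- stats::lm.fit(X, yy)
  cf <- fit$coefficients[-1]
  theta <- cf[seq_along(pn)]; names(theta) <- pn
  theta_pair <- cf[length(pn) + seq_len(ncol(pairs))]
  names(theta_pair) <- pname
  theta_pair[is.na(theta_pair)] <- 0
  tot <- sum(theta^2) + sum(theta_pair^2)
  if (tot < 1e-300)
    stop("all coefficients are zero; Sobol indices undefined", call. = FALSE)
  structure(list(theta = theta, theta_pair = theta_pair,
                 S = theta^2 / tot, S_pair = theta_pair^2 / tot,
                 design = design),
            class = c("local_sobol_result", "list"))
}

#' Bounded multi-start Nelder-Mead calibration
#'
#' Minimizes a cost over a parameter subset with the simplex algorithm,
#' clamping candidates to physical bounds (with a quadratic penalty for the
#' excursion, so the optimizer is steered back inside). Several starting
#' points guard against local minima; the best result is returned.
#'
#' @param cost_fn Function of a named numeric vector returning the cost.
#' @param starts List of named numeric start vectors (or a single vector).
#' @param lower,upper Named bound vectors.
#' @param maxit Iteration cap per start.
#' @param reltol Simplex convergence tolerance.
#' @return List with `par` (clamped optimum), `value`, `at_bound` (logical
#'   per parameter), `starts` (per-start diagnostics).
#' @export
calibrate <- function(cost_fn, starts, lower, upper, maxit = 200,
                      reltol = 1e-8) {
  if (!is.list(starts)) starts <- list(starts)
  pn <- names(starts[[1]])
  stopifnot(!is.null(pn), all(pn %in% names(lower)),
            all(pn %in% names(upper)))
  lo <- lower[pn]; hi <- upper[pn]
  pen_cost <- function(p) {
    pc <- pmin(pmax(p, lo), hi)
    viol <- sum(((p - pc) / pmax(abs(hi - lo), 1e-300))^2)
    val <- tryCatch(cost_fn(pc), error = function(e) NA_real_)
    if (!is.finite(val)) return(1e300)
    val * (1 + 100 * viol) + viol
  }
  scale0 <- pmax(abs(hi - lo) / 10, 1e-12)
  res <- lapply(starts, function(s0) {
    f0 <- pen_cost(s0[pn])
    # fnscale makes the simplex tolerance relative to the starting cost,
    # which for SI-unit volume mismatches can be ~1e-23
    fs <- if (is.finite(f0) && f0 > 0 && f0 < 1e300) f0 else 1
    ps <- ifelse(abs(s0[pn]) > 0, abs(s0[pn]), scale0)
    tryCatch(stats::optim(s0[pn], pen_cost, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = reltol,
                                         fnscale = fs, parscale = ps)),
             error = function(e) list(value = Inf, par = s0[pn],
                                      error = conditionMessage(e)))
  })
  vals <- vapply(res, `[[`, numeric(1), "value")
  if (all(!is.finite(vals) | vals >= 1e300))
    stop("calibration failed for every start", call. = FALSE)
  best <- res[[which.min(vals)]]
  par <- pmin(pmax(best$par, lo), hi)
  tol_b <- 1e-6 * pmax(abs(hi - lo), 1e-300)
  list(par = par,
       value = tryCatch(cost_fn(par), error = function(e) NA_real_),
       at_bound = (par <= lo + tol_b) | (par >= hi - tol_b),
       starts = res)
}

#' Two-stage identification of the cell-line parameters
#'
#' Stage 1 fits the growth rate, metabolic oxygen consumption and
#' saturation parameter (`gamma_gt`, `gamma_0nl`, `a`) on free-growth
#' volume data; stage 2 freezes them and fits the pressure thresholds
#' (`p1`, `p_crit`) on confined data (inner-wall displacement and
#' confinement pressure one day after confluence).
#'
#' @param free_data Free-growth series for [cost_free()].
#' @param conf_data Confined observations for [cost_conf()].
#' @param base A [cell_line_parameters()] baseline (start of stage 1).
#' @param free_runner,conf_runner Functions mapping a
#'   [cell_line_parameters()] object to a `simulation_result` for the two
#'   configurations.
#' @param span Relative start spread: starts at the baseline and at
#'   `(1 +/- span)` times it for stage 1 (the pressure thresholds use
#'   `2.5 span`, reflecting their larger prior uncertainty).
#' @param bounds_factor Multiplicative half-width of the parameter bounds.
#' @param maxit Simplex iteration cap per start.
#' @param multi_start Use the spread starts (otherwise baseline only).
#' @return List with `cell_line` (identified [cell_line_parameters()]),
#'   `stage1`, `stage2` (each a [calibrate()] result).
#' @export
staged_identification <- function(free_data, conf_data, base,
                                  free_runner, conf_runner,
                                  span = 0.2, bounds_factor = 4,
                                  maxit = 150, multi_start = FALSE) {
  validate_cell_line_parameters(base)
  upd <- function(cl, p) {
    for (nm in names(p)) cl[[nm]] <- unname(p[nm])
    cl
  }
  mk_starts <- function(v, sp) {
    if (!multi_start) return(list(v))
    list(v, v * (1 + sp), v * (1 - sp))
  }
  # stage 1: free growth
  p1v <- c(gamma_gt = base$gamma_gt, gamma_0nl = base$gamma_0nl, a = base$a)
  cost1 <- function(p) cost_free(free_runner(upd(base, p)), free_data)
  st1 <- calibrate(cost1, mk_starts(p1v, span),
                   lower = p1v / bounds_factor, upper = p1v * bounds_factor,
                   maxit = maxit)
  cl1 <- upd(base, st1$par)
  # stage 2: confinement, stage-1 parameters frozen
  p2v <- c(p1 = base$p1, p_crit = base$p_crit)
  cost2 <- function(p) {
    if (p["p1"] >= p["p_crit"]) return(1e300)   # invalid ordering rejected
    cost_conf(conf_runner(upd(cl1, p)), conf_data)
  }
  st2 <- calibrate(cost2, mk_starts(p2v, 2.5 * span),
                   lower = p2v / bounds_factor, upper = p2v * bounds_factor,
                   maxit = maxit)
  cl2 <- upd(cl1, st2$par)
  validate_cell_line_parameters(cl2)
  list(cell_line = cl2, stage1 = st1, stage2 = st2)
}
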