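# Monolithic implicit solver for the coupled four-field system
# (u_s, p_l, p_tl, omega_nl) on the 1-D spherically-symmetric (or Cartesian)
# mesh. Quadratic displacement / linear scalars, 3-point Gauss quadrature,
# implicit Euler in time, Newton with a colored finite-difference Jacobian,
# updated-Lagrangian geometry increments.

.elem_props <- function(mesh, domain) {
  mat <- domain$materials
  tag <- mesh$subdomain
  get1 <- function(f) vapply(tag, function(s) mat[[s]][[f]], numeric(1),
                             USE.NAMES = FALSE)
  E <- get1("E"); nu <- get1("nu")
  lm <- lame_constants(E, nu)
  af <- vapply(tag, function(s) {
    v <- mat[[s]][["a_factor"]]
    if (is.null(v)) 1 else v
  }, numeric(1), USE.NAMES = FALSE)
  list(lambda = lm$lambda, mu = lm$mu,
       k = get1("k"), kt = get1("k") * get1("k_t_factor"),
       eps0 = get1("eps0"), a_factor = af)
}

.solver_cfg <- function(disc, active_ptl = TRUE, active_om = TRUE,
                        traction = 0, reuse_jacobian = FALSE,
                        active_pl = TRUE) {
  list(small_strain = isTRUE(disc$small_strain),
       c_reg = disc$c_reg, krel_floor = disc$krel_floor,
       D_floor = if (is.null(disc$D_floor)) 0.05 else disc$D_floor,
       active_pl = active_pl, active_ptl = active_ptl,
       active_om = active_om,
       traction = traction, reuse_jacobian = reuse_jacobian,
       newton_tol = disc$newton_tol, newton_max = disc$newton_max)
}

#' Initialize the simulation state
#'
#' Fields start from the quiescent, fully oxygenated configuration: oxygen at
#' the environmental mass fraction everywhere, zero IF pressure, zero
#' displacement, reference porosity, no necrosis. The cell/IF pressure
#' difference is set to `a tan(pi S_t0 / 2)` inside the seed radius (so the
#' seed starts at saturation `S_t0`), smoothed to zero over the transition
#' width, and zero outside: the exterior holds no cell phase.
#'
#' @param domain A [domain_spec()].
#' @param disc A [discretization()].
#' @param params A [model_parameters()].
#' @return Object of class `sim_state`.
#' @export
initialize_state <- function(domain, disc, params) {
  stopifnot(inherits(params, "model_parameters"))
  mesh <- build_mesh(domain, disc)
  props <- .elem_props(mesh, domain)
  cl <- params$cell_line
  r <- mesh$nodes
  w <- domain$transition_width
  p_tl0 <- cl$a * tan(pi * domain$S_t0 / 2)
  ramp <- function(r) {
    x <- (r - (domain$R_seed - w)) / w
    ifelse(x <= 0, 1, ifelse(x >= 1, 0, 0.5 + 0.5 * cos(pi * x)))
  }
  ptl <- p_tl0 * ramp(r)
  pl <- numeric(mesh$ns)
  om <- rep(cl$omega_env, mesh$ns)
  ne <- mesh$nelem
  qz <- matrix(0, ne, 3)
  eps_q <- matrix(props$eps0, ne, 3)
  ptl_q <- matrix(ptl[mesh$smap], ne, 2) %*% t(mesh$N1)
  St_q <- cell_saturation(ptl_q, 0, cl$a)
  om_q <- matrix(om[mesh$smap], ne, 2) %*% t(mesh$N1)
  st <- list(time = 0, mesh = mesh, domain = domain, props = props,
             u = numeric(mesh$nu), pl = pl, ptl = ptl, om = om,
             J_q = qz + 1, eps_q = eps_q, omNt_q = qz,
             sig_rr_q = qz, sig_tt_q = qz,
             St_q = St_q, eSlom_q = eps_q * (1 - St_q) * om_q,
             last_du = numeric(mesh$nu))
  class(st) <- c("sim_state", "list")
  st
}

# Derived quadrature-point fields for a trial solution. Returns everything
# the residual and the state update need.
.derived_q <- function(st, x, dt, params, cfg) {
  mesh <- st$mesh; ne <- mesh$nelem
  pow <- if (mesh$geometry == "spherical") 2L else 0L
  cl <- params$cell_line; ph <- params$phases; pr <- st$props
  nu <- mesh$nu; ns <- mesh$ns
  du <- x[seq_len(nu)]
  pl <- x[nu + seq_len(ns)]
  ptl <- x[nu + ns + seq_len(ns)]
  om <- x[nu + 2L * ns + seq_len(ns)]
  h_e <- diff(mesh$nodes); detJ <- h_e / 2
  rv <- cbind(mesh$nodes[seq_len(ne)], mesh$nodes[seq_len(ne) + 1L])
  r_q <- rv %*% t(mesh$N1)
  wq <- matrix(mesh$gw, ne, 3, byrow = TRUE) * detJ
  if (pow == 2L) wq <- wq * r_q^2
  Ue <- matrix(du[mesh$umap], ne, 3)
  du_q <- Ue %*% t(mesh$N2)
  ddu_q <- (Ue %*% t(mesh$dN2)) / detJ
  g1 <- function(v) {
    Ve <- matrix(v[mesh$smap], ne, 2)
    list(v = Ve %*% t(mesh$N1), d = (Ve %*% t(mesh$dN1)) / detJ)
  }
  PL <- g1(pl); PTL <- g1(ptl); OM <- g1(om)
  if (cfg$small_strain) {
    Jn <- st$J_q; epsn <- st$eps_q
  } else {
    Jinc <- if (pow == 2L) (1 + ddu_q) * (1 + du_q / r_q)^2 else 1 + ddu_q
    Jn <- st$J_q * Jinc
    epsn <- pmax(1 - (1 - pr$eps0) / pmax(Jn, 1e-6), 1e-3)
  }
  omNt <- st$omNt_q
  # signed arctan closure: keeps the cell-phase equation non-degenerate
  # where the phase vanishes (S_t <= 0 there); sources and conductivities
  # are floored at zero so no spurious cell mass is created
  St <- (2 / pi) * atan(PTL$v / ((1 - omNt) * cl$a * pr$a_factor))
  Stp <- pmax(St, 0)
  Sl <- 1 - St
  pt_q <- PL$v + PTL$v
  ps_q <- St * pt_q + Sl * PL$v
  divv <- if (pow == 2L) (ddu_q + 2 * du_q / r_q) / dt else ddu_q / dt
  # the liquid keeps a residual connectivity (floor on its relative
  # permeability) so the last IF in a packed necrotic core can still drain
  Kl <- (pr$k * pmax(pmin(Sl, 1)^ph$A_l, 1e-3)) / ph$mu_l
  Kt <- (pr$kt * pmax(Stp^ph$A_t, cfg$krel_floor)) / cl$mu_t
  xo <- pmin(pmax((OM$v - cl$omega_crit) / (cl$omega_env - cl$omega_crit),
                  0), 1)
  H <- 0.5 - 0.5 * cos(pi * xo)
  Hp <- pmin(pmax((pt_q - cl$p1) / (cl$p_crit - cl$p1), 0), 1)
  Ht <- ifelse(OM$v >= cl$omega_env, 1,
               0.5 - 0.5 * cos(pi * pmax(OM$v, 0) / cl$omega_env))
  live <- (1 - omNt) * epsn * Stp
  Mgr <- cl$gamma_gt * H * (1 - Hp) * live
  Sink <- (cl$gamma_gnl * H * (1 - Hp) + cl$gamma_0nl * Ht) * live
  # floor on (eps S_l) keeps the oxygen equation non-degenerate in the
  # fully packed necrotic core where the IF fraction vanishes
  Dnl <- ph$D0_nl * pmin(pmax(epsn * Sl, cfg$D_floor), 1)^ph$delta
  list(ne = ne, pow = pow, detJ = detJ, r_q = r_q, wq = wq,
       du_q = du_q, ddu_q = ddu_q, pl_q = PL$v, dpl_q = PL$d,
       ptl_q = PTL$v, dptl_q = PTL$d, om_q = OM$v, dom_q = OM$d,
       Jn = Jn, epsn = epsn, St = St, Sl = Sl, pt_q = pt_q, ps_q = ps_q,
       divv = divv, Kl = Kl, Kt = Kt, H = H, Hp = Hp, Ht = Ht,
       Mgr = Mgr, Sink = Sink, Dnl = Dnl)
}

# Full (unconstrained) residual vector for a trial solution x given the
# converged state st at the previous time level.
.residual_full <- function(st, x, dt, params, cfg, d = NULL) {
  mesh <- st$mesh
  cl <- params$cell_line; ph <- params$phases; pr <- st$props
  if (is.null(d)) d <- .derived_q(st, x, dt, params, cfg)
  ne <- d$ne
  nu <- mesh$nu; ns <- mesh$ns
  o_pl <- nu; o_ptl <- nu + ns; o_om <- nu + 2L * ns
  wq <- d$wq; detJ <- d$detJ
  mSt_old <- st$eps_q * st$St_q
  ptl_old_q <- matrix(st$ptl[mesh$smap], ne, 2) %*% t(mesh$N1)
  dpt_q <- d$dpl_q + d$dptl_q

  # summed (solid + both fluids) mass balance -> p_l rows
  IA <- wq * (d$divv - d$Mgr * (1 / ph$rho_t - 1 / ph$rho_l))
  FA <- wq * (d$Kt * dpt_q + d$Kl * d$dpl_q)
  cA <- IA %*% mesh$N1 + (FA %*% mesh$dN1) / detJ

  # tumor-cell-phase mass balance -> p_tl rows
  IB <- wq * ((d$epsn * d$St - mSt_old) / dt + d$epsn * d$St * d$divv -
                d$Mgr / ph$rho_t +
                cfg$c_reg * (d$ptl_q - ptl_old_q) / dt)
  FB <- wq * (d$Kt * dpt_q)
  cB <- IB %*% mesh$N1 + (FB %*% mesh$dN1) / detJ

  # oxygen advection-diffusion -> omega rows
  IC <- wq * ((d$epsn * d$Sl * d$om_q - st$eSlom_q) / dt +
                d$epsn * d$Sl * d$om_q * d$divv + d$Sink / ph$rho_l)
  FC <- wq * (d$Dnl * d$epsn * d$Sl * d$dom_q + d$om_q * d$Kl * d$dpl_q)
  cC <- IC %*% mesh$N1 + (FC %*% mesh$dN1) / detJ

  # total momentum with Biot split -> u rows
  lam <- pr$lambda; mu2 <- pr$mu
  if (d$pow == 2L) {
    srr <- st$sig_rr_q + (lam + 2 * mu2) * d$ddu_q +
      2 * lam * (d$du_q / d$r_q)
    stt <- st$sig_tt_q + lam * (d$ddu_q + 2 * d$du_q / d$r_q) +
      2 * mu2 * (d$du_q / d$r_q)
    cD <- ((wq * (srr - d$ps_q)) %*% mesh$dN2) / detJ +
      (wq * (2 * (stt - d$ps_q) / d$r_q)) %*% mesh$N2
  } else {
    srr <- st$sig_rr_q + (lam + 2 * mu2) * d$ddu_q
    cD <- ((wq * (srr - d$ps_q)) %*% mesh$dN2) / detJ
  }

  res <- numeric(nu + 3L * ns)
  for (a in 1:2) {
    idx <- mesh$smap[, a]
    res[o_pl + idx] <- res[o_pl + idx] + cA[, a]
    res[o_ptl + idx] <- res[o_ptl + idx] + cB[, a]
    res[o_om + idx] <- res[o_om + idx] + cC[, a]
  }
  for (a in 1:3) {
    idx <- mesh$umap[, a]
    res[idx] <- res[idx] + cD[, a]
  }
  if (cfg$traction != 0) res[nu] <- res[nu] + cfg$traction
  res
}

#' Assemble the weak-form residual of the coupled system
#'
#' Evaluates the implicit-Euler weak-form residual of the four governing
#' equations (summed mass balance, tumor-phase mass balance, oxygen
#' advection-diffusion, total momentum with the Biot effective-stress split)
#' for `state` as the trial solution one step of length `dt` after
#' `prev_state`. A converged step has a (free-dof) residual at solver
#' tolerance.
#'
#' @param state Trial `sim_state` (the end-of-step solution).
#' @param prev_state Converged `sim_state` at the previous time level.
#' @param dt Time-step length, s.
#' @param params A [model_parameters()].
#' @return Full residual vector (displacement rows first, then the three
#'   scalar blocks).
#' @export
assemble_residual <- function(state, prev_state, dt, params) {
  stopifnot(inherits(state, "sim_state"), inherits(prev_state, "sim_state"))
  for (f in c("u", "pl", "ptl", "om")) {
    if (any(!is.finite(state[[f]])))
      stop("non-finite values in field '", f, "'", call. = FALSE)
  }
  cfg <- list(small_strain = FALSE, c_reg = 0, krel_floor = 1e-6,
              D_floor = 0.05, traction = 0)
  x <- c(state$u - prev_state$u, state$pl, state$ptl, state$om)
  .residual_full(prev_state, x, dt, params, cfg)
}

# Dirichlet bookkeeping: indices and values of fixed dofs for one step.
.fixed_dofs <- function(st, params, cfg) {
  mesh <- st$mesh
  nu <- mesh$nu; ns <- mesh$ns
  cl <- params$cell_line
  idx <- c(1L, nu)          # radial symmetry / fixed outer displacement
  val <- c(0, 0)
  if (mesh$geometry == "cartesian") { idx <- c(1L); val <- c(0) }
  if (isTRUE(cfg$active_pl) || is.null(cfg$active_pl)) {
    idx <- c(idx, nu + ns); val <- c(val, 0)          # p_l = 0 outer
  } else {
    idx <- c(idx, nu + seq_len(ns)); val <- c(val, st$pl)
  }
  if (cfg$active_ptl) {
    idx <- c(idx, nu + 2L * ns); val <- c(val, 0)     # p_tl = 0 outer
  } else {
    idx <- c(idx, nu + ns + seq_len(ns)); val <- c(val, st$ptl)
  }
  if (cfg$active_om) {
    idx <- c(idx, nu + 3L * ns); val <- c(val, cl$omega_env)
  } else {
    idx <- c(idx, nu + 2L * ns + seq_len(ns)); val <- c(val, st$om)
  }
  list(idx = idx, val = val)
}

# Column scales per dof (FD step sizes and convergence metric).
.col_scales <- function(mesh, params) {
  c(rep(1e-6, mesh$nu), rep(1e3, mesh$ns), rep(1e3, mesh$ns),
    rep(params$cell_line$omega_env, mesh$ns))
}

# Greedy coloring of the free columns so dofs with disjoint element stars
# share a finite-difference evaluation; star rows for the Jacobian fill.
.fd_structure <- function(mesh, free) {
  ne <- mesh$nelem; nu <- mesh$nu; ns <- mesh$ns
  ntot <- nu + 3L * ns
  elems_of <- vector("list", ntot)
  add <- function(dof, e) elems_of[[dof]] <<- c(elems_of[[dof]], e)
  for (e in seq_len(ne)) {
    for (dof in mesh$umap[e, ]) add(dof, e)
    for (v in mesh$smap[e, ]) {
      add(nu + v, e); add(nu + ns + v, e); add(nu + 2L * ns + v, e)
    }
  }
  dofs_of_elem <- lapply(seq_len(ne), function(e)
    c(mesh$umap[e, ], nu + mesh$smap[e, ], nu + ns + mesh$smap[e, ],
      nu + 2L * ns + mesh$smap[e, ]))
  freepos <- integer(ntot); freepos[free] <- seq_along(free)
  colors <- list(); occ <- list()
  color_of <- integer(ntot)
  for (dof in free) {
    es <- elems_of[[dof]]
    # two columns conflict if any residual row sees both, i.e. if their
    # element stars touch a common dof: occupy the neighbors as well
    esx <- unique(pmin(pmax(c(es - 1L, es, es + 1L), 1L), ne))
    placed <- FALSE
    for (c in seq_along(colors)) {
      if (!any(occ[[c]][esx])) {
        colors[[c]] <- c(colors[[c]], dof); occ[[c]][esx] <- TRUE
        color_of[dof] <- c; placed <- TRUE; break
      }
    }
    if (!placed) {
      colors[[length(colors) + 1L]] <- dof
      o <- logical(ne); o[esx] <- TRUE
      occ[[length(colors)]] <- o
      color_of[dof] <- length(colors)
    }
  }
  rowstar <- lapply(seq_len(ntot), function(dof) {
    rs <- unique(unlist(dofs_of_elem[elems_of[[dof]]]))
    sort(freepos[rs[freepos[rs] > 0L]])
  })
  list(colors = colors, rowstar = rowstar, freepos = freepos)
}

.build_jacobian <- function(st, x, dt, params, cfg, free, fd, cs, r0f) {
  nfree <- length(free)
  J <- matrix(0, nfree, nfree)
  hs <- 1e-6 * cs
  for (cols in fd$colors) {
    xh <- x
    xh[cols] <- xh[cols] + hs[cols]
    rhf <- .residual_full(st, xh, dt, params, cfg)[free]
    dr <- rhf - r0f
    for (dof in cols) {
      rows <- fd$rowstar[[dof]]
      J[rows, fd$freepos[dof]] <- dr[rows] / hs[dof]
    }
  }
  J
}

# One Newton solve of the time step. Returns list(x, res_full, iters,
# converged). `cache` is an environment for Jacobian reuse.
.newton_step <- function(st, x0, dt, params, cfg, free, fixed, fd, cs,
                         cache) {
  x <- x0
  x[fixed$idx] <- fixed$val
  csf <- cs[free]
  for (it in seq_len(cfg$newton_max)) {
    res <- .residual_full(st, x, dt, params, cfg)
    r0f <- res[free]
    if (!all(is.finite(r0f))) return(list(converged = FALSE, iters = it))
    if (is.null(cache$Jqr) || !cache$valid) {
      J <- .build_jacobian(st, x, dt, params, cfg, free, fd, cs, r0f)
      J <- J * rep(csf, each = nrow(J))      # column equilibration
      s <- 1 / pmax(apply(abs(J), 1, max), 1e-300)
      cache$Jqr <- tryCatch(qr(J * s), error = function(e) NULL)
      if (is.null(cache$Jqr) || cache$Jqr$rank < length(free))
        return(list(converged = FALSE, iters = it))
      cache$s <- s
      cache$valid <- TRUE
    }
    dx <- qr.coef(cache$Jqr, r0f * cache$s) * csf
    if (any(!is.finite(dx))) {
      cache$valid <- FALSE
      return(list(converged = FALSE, iters = it))
    }
    err <- max(abs(dx) / csf)
    norm0 <- max(abs(r0f * cache$s))
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:7) {
      xt <- x
      xt[free] <- x[free] - alpha * dx
      rtf <- .residual_full(st, xt, dt, params, cfg)[free]
      if (all(is.finite(rtf)) &&
          (max(abs(rtf * cache$s)) < norm0 || err * alpha < cfg$newton_tol)) {
        x <- xt; accepted <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      if (cfg$reuse_jacobian && cache$valid) {
        # stale Jacobian: force a rebuild and retry this iteration
        cache$valid <- FALSE
        next
      }
      return(list(converged = FALSE, iters = it))
    }
    if (!cfg$reuse_jacobian) cache$valid <- FALSE
    if (err * alpha < cfg$newton_tol) {
      res <- .residual_full(st, x, dt, params, cfg)
      return(list(x = x, res_full = res, iters = it, converged = TRUE))
    }
  }
  list(converged = FALSE, iters = cfg$newton_max)
}

# Commit a converged solution x into a new state (geometry, internal
# variables, stresses, necrosis update).
.commit_step <- function(st, x, dt, params, cfg) {
  mesh <- st$mesh
  cl <- params$cell_line; ph <- params$phases; pr <- st$props
  nu <- mesh$nu; ns <- mesh$ns
  d <- .derived_q(st, x, dt, params, cfg)
  du <- x[seq_len(nu)]
  new <- st
  new$time <- st$time + dt
  new$u <- st$u + du
  new$pl <- x[nu + seq_len(ns)]
  new$ptl <- x[nu + ns + seq_len(ns)]
  new$om <- x[nu + 2L * ns + seq_len(ns)]
  if (!cfg$small_strain) {
    new$mesh$nodes <- mesh$nodes + du[seq(1L, nu, by = 2L)]
    new$J_q <- d$Jn
    new$eps_q <- d$epsn
  }
  lam <- pr$lambda; mu2 <- pr$mu
  if (d$pow == 2L) {
    new$sig_rr_q <- st$sig_rr_q + (lam + 2 * mu2) * d$ddu_q +
      2 * lam * (d$du_q / d$r_q)
    new$sig_tt_q <- st$sig_tt_q + lam * (d$ddu_q + 2 * d$du_q / d$r_q) +
      2 * mu2 * (d$du_q / d$r_q)
  } else {
    new$sig_rr_q <- st$sig_rr_q + (lam + 2 * mu2) * d$ddu_q
  }
  # necrotic fraction: pointwise implicit update with growth dilution
  # (gamma_Nt is a mass rate, kg/(m^3 s); per unit living mass it gives
  # the fraction rate gamma_Nt (1 - Htilde) / rho_t)
  gam <- cl$gamma_Nt * (1 - d$Ht) / ph$rho_t
  mliv <- d$epsn * d$St
  gdil <- ifelse(mliv > 1e-8, d$Mgr / (ph$rho_t * pmax(mliv, 1e-8)), 0)
  new$omNt_q <- (st$omNt_q + dt * gam) / (1 + dt * gam + dt * gdil)
  new$omNt_q <- pmin(pmax(new$omNt_q, 0), 1 - 1e-9)
  new$St_q <- d$St
  new$eSlom_q <- d$epsn * d$Sl * d$om_q
  new$last_du <- du
  new
}

#' Advance the simulation by one time step
#'
#' Performs one implicit-Euler step of the monolithic Newton solver. On
#' Newton divergence the step is rejected and retried with a halved time
#' step (up to `max_dt_halvings`), the sub-steps being composed to cover
#' `dt`.
#'
#' @param state A converged `sim_state`.
#' @param disc A [discretization()].
#' @param params A [model_parameters()].
#' @param active_ptl,active_om Solve (TRUE) or freeze (FALSE) the cell
#'   pressure-difference and oxygen fields; freezing both reduces the kernel
#'   to single-fluid poroelasticity.
#' @param traction Compressive load magnitude applied at the outer boundary
#'   (Cartesian consolidation kernel), Pa.
#' @param cache Optional environment carrying the Jacobian between calls.
#' @return The advanced `sim_state`; attribute `"newton_iters"` reports the
#'   iteration count.
#' @export
advance_step <- function(state, disc, params, active_ptl = TRUE,
                         active_om = TRUE, traction = 0, cache = NULL) {
  cfg <- .solver_cfg(disc, active_ptl, active_om, traction,
                     reuse_jacobian = !is.null(cache))
  cfg$small_strain <- isTRUE(disc$small_strain)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$valid)) cache$valid <- FALSE
  mesh <- state$mesh
  cs <- .col_scales(mesh, params)
  fixed <- .fixed_dofs(state, params, cfg)
  free <- setdiff(seq_len(mesh$nu + 3L * mesh$ns), fixed$idx)
  if (is.null(cache$fd)) cache$fd <- .fd_structure(mesh, free)
  dt_left <- disc$dt
  dt_try <- disc$dt
  halvings <- 0L
  st <- state
  iters_total <- 0L
  while (dt_left > 1e-9 * disc$dt) {
    x0 <- c(st$last_du * (dt_try / disc$dt), st$pl, st$ptl, st$om)
    out <- .newton_step(st, x0, dt_try, params, cfg, free, fixed,
                        cache$fd, cs, cache)
    if (out$converged) {
      st <- .commit_step(st, out$x, dt_try, params, cfg)
      st$res_full <- out$res_full
      iters_total <- iters_total + out$iters
      dt_left <- dt_left - dt_try
    } else {
      halvings <- halvings + 1L
      cache$valid <- FALSE
      if (halvings > disc$max_dt_halvings)
        stop("Newton failed to converge after ", halvings - 1L,
             " dt halvings at t = ", st$time, " s", call. = FALSE)
      dt_try <- dt_try / 2
    }
  }
  attr(st, "newton_iters") <- iters_total
  st
}

# Nodal projections of quadrature internal variables (adjacent-element mean).
.q_to_nodes <- function(mesh, q) {
  ne <- mesh$nelem
  em <- rowMeans(q)
  v <- numeric(ne + 1L)
  v[1] <- em[1]; v[ne + 1L] <- em[ne]
  if (ne > 1L) v[2:ne] <- (em[1:(ne - 1L)] + em[2:ne]) / 2
  v
}

# Outermost radius where nodal S_t crosses half its maximum.
.front_radius <- function(r, St) {
  thr <- 0.5 * max(St)
  if (max(St) <= 0) return(0)
  above <- St >= thr
  i <- max(which(above))
  if (i == length(r)) return(r[i])
  # linear interpolation of the crossing
  f <- (thr - St[i + 1]) / (St[i] - St[i + 1])
  r[i + 1] + f * (r[i] - r[i + 1])
}

.snapshot <- function(st, params) {
  mesh <- st$mesh
  cl <- params$cell_line
  omNt_n <- .q_to_nodes(mesh, st$omNt_q)
  eps_n <- .q_to_nodes(mesh, st$eps_q)
  # nodal saturation from the nodal pressure difference; at a material
  # interface the node takes the more permissive (lumen) side
  af <- st$props$a_factor
  ne <- mesh$nelem
  af_n <- pmin(c(af[1], af), c(af, af[ne]))
  St_n <- pmin(pmax((2 / pi) * atan(st$ptl /
                                      ((1 - omNt_n) * cl$a * af_n)), 0), 1)
  list(time = st$time, r = mesh$nodes,
       u_s = st$u[seq(1L, mesh$nu, by = 2L)],
       p_l = st$pl, p_tl = st$ptl, omega_nl = st$om,
       S_t = St_n, omega_Nt = omNt_n, eps = eps_n,
       p_t = st$pl + st$ptl,
       omega_grow = growing_fraction(st$om, St_n, cl))
}

# Mechanical pre-equilibration: solve the momentum equation alone (all
# scalar fields frozen at their initial values) so time stepping starts
# from a stress state balancing the initial solid pressure.
.equilibrate <- function(st, disc, params) {
  cfg <- .solver_cfg(disc, active_ptl = FALSE, active_om = FALSE,
                     active_pl = FALSE)
  mesh <- st$mesh
  cs <- .col_scales(mesh, params)
  fixed <- .fixed_dofs(st, params, cfg)
  free <- setdiff(seq_len(mesh$nu + 3L * mesh$ns), fixed$idx)
  fd <- .fd_structure(mesh, free)
  cache <- new.env(parent = emptyenv()); cache$valid <- FALSE
  x0 <- c(numeric(mesh$nu), st$pl, st$ptl, st$om)
  out <- .newton_step(st, x0, 1e-6, params, cfg, free, fixed, fd, cs, cache)
  if (!out$converged) {
    warning("mechanical pre-equilibration did not converge; ",
            "starting from the unstressed state")
    return(st)
  }
  new <- .commit_step(st, out$x, 1e-6, params, cfg)
  new$time <- st$time
  new$last_du <- numeric(mesh$nu)
  # the scalar storage states follow the equilibrated porosity
  d <- .derived_q(st, out$x, 1e-6, params, cfg)
  new$eSlom_q <- d$epsn * d$Sl * d$om_q
  new
}

#' Run a full growth simulation
#'
#' Time-steps the coupled system from [initialize_state()] to the horizon,
#' recording scalar summaries every `save_every` steps and full radial
#' snapshots every `snapshot_every` steps. Confluence is detected as the
#' first time the tumor front (outermost radius where the cell saturation
#' exceeds half its maximum) reaches the capsule inner wall.
#'
#' @param domain A [domain_spec()].
#' @param disc A [discretization()].
#' @param params A [model_parameters()].
#' @param quiet Suppress progress messages.
#' @return Object of class `simulation_result`: `series` (data.frame of
#'   scalar time series), `snapshots`, `confluence_time_s`, diagnostic
#'   maxima, and the inputs.
#' @export
run_simulation <- function(domain, disc, params, quiet = TRUE) {
  st <- initialize_state(domain, disc, params)
  st <- .equilibrate(st, disc, params)
  mesh <- st$mesh
  cl <- params$cell_line
  nsteps <- ceiling(disc$t_end / disc$dt)
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nsteps + 1L)
  snaps <- list()
  shell_el <- which(mesh$subdomain == "alginate")
  band_el <- if (domain$encapsulated)
    pmax(mesh$interface_in - c(2L, 1L), 1L) else integer(0)
  confluence <- NA_real_
  max_shell_St <- 0
  max_mass_err <- 0
  min_oxygen <- Inf
  record <- function(st) {
    snap <- .snapshot(st, params)
    wq <- .quad_weights(st$mesh)
    # signed integral: the discretely conserved cell-phase measure (the
    # small negative closure dip ahead of the front is part of the balance)
    Vt <- 4 * pi * sum(wq * st$eps_q * st$St_q)
    Rm <- .front_radius(snap$r, snap$S_t)
    if (domain$encapsulated) {
      Rin <- st$mesh$nodes[mesh$interface_in]
      Rout <- st$mesh$nodes[mesh$interface_out]
      wb <- wq[band_el, , drop = FALSE]
      ptl_b <- matrix(st$ptl[mesh$smap[band_el, , drop = FALSE]],
                      length(band_el), 2) %*% t(mesh$N1)
      pl_b <- matrix(st$pl[mesh$smap[band_el, , drop = FALSE]],
                     length(band_el), 2) %*% t(mesh$N1)
      St_b <- cell_saturation(ptl_b, st$omNt_q[band_el, , drop = FALSE],
                              cl$a)
      pt_b <- pl_b + ptl_b
      ps_b <- St_b * pt_b + (1 - St_b) * pl_b
      sg_b <- st$sig_rr_q[band_el, , drop = FALSE]
      wsum <- sum(wb)
      pt_w <- sum(wb * pt_b) / wsum
      ps_w <- sum(wb * ps_b) / wsum
      srr_w <- sum(wb * (sg_b - ps_b)) / wsum
    } else {
      Rin <- NA_real_; Rout <- NA_real_
      pt_w <- NA_real_; ps_w <- NA_real_; srr_w <- NA_real_
    }
    list(time_s = st$time, V_tumor_m3 = Vt, R_mcts_m = Rm,
         R_in_m = Rin, R_out_m = Rout,
         p_t_wall_Pa = pt_w, p_s_wall_Pa = ps_w, sigma_rr_wall_Pa = srr_w,
         p_l_min_Pa = min(st$pl), p_l_max_Pa = max(st$pl),
         omega_center = st$om[1])
  }
  rows[[1L]] <- record(st)
  snaps[[1L]] <- .snapshot(st, params)
  kept <- 1L
  for (n in seq_len(nsteps)) {
    st <- advance_step(st, disc, params, cache = cache)
    min_oxygen <- min(min_oxygen, min(st$om))
    if (length(shell_el))
      max_shell_St <- max(max_shell_St, max(st$St_q[shell_el, ]))
    if (!is.null(st$res_full)) {
      # discrete tumor-phase mass budget: interior residual of the
      # cell-phase balance, relative to the phase mass turnover scale
      fixed <- .fixed_dofs(st, params, .solver_cfg(disc))
      nu <- mesh$nu; ns <- mesh$ns
      rB <- st$res_full[nu + ns + seq_len(ns)]
      rB[fixed$idx[fixed$idx > nu + ns & fixed$idx <= nu + 2L * ns] -
           nu - ns] <- 0
      wq <- .quad_weights(st$mesh)
      Mt <- sum(wq * st$eps_q * st$St_q)
      max_mass_err <- max(max_mass_err,
                          abs(sum(rB)) * disc$dt / max(Mt, 1e-30))
    }
    if (n %% disc$save_every == 0L || n == nsteps) {
      kept <- kept + 1L
      rows[[kept]] <- record(st)
    }
    if (n %% disc$snapshot_every == 0L || n == nsteps)
      snaps[[length(snaps) + 1L]] <- .snapshot(st, params)
    if (domain$encapsulated && is.na(confluence)) {
      lastrow <- rows[[kept]]
      if (!is.null(lastrow) && lastrow$time_s == st$time &&
          lastrow$R_mcts_m >= lastrow$R_in_m) confluence <- st$time
    }
    if (!quiet && n %% 50L == 0L)
      message(sprintf("t = %.2f d", st$time / 86400))
  }
  series <- do.call(rbind, lapply(rows[seq_len(kept)], as.data.frame))
  structure(list(series = series, snapshots = snaps,
                 confluence_time_s = confluence,
                 encapsulated = domain$encapsulated,
                 max_shell_St = max_shell_St,
                 max_mass_err = max_mass_err,
                 min_oxygen = min_oxygen,
                 final_state = st,
                 domain = domain, disc = disc, params = params),
            class = c("simulation_result", "list"))
}

.quad_weights <- function(mesh) {
  ne <- mesh$nelem
  detJ <- diff(mesh$nodes) / 2
  rv <- cbind(mesh$nodes[seq_len(ne)], mesh$nodes[seq_len(ne) + 1L])
  r_q <- rv %*% t(mesh$N1)
  wq <- matrix(mesh$gw, ne, 3, byrow = TRUE) * detJ
  if (mesh$geometry == "spherical") wq <- wq * r_q^2
  wq
}

#' Probe a field along the radius at a stored snapshot time
#'
#' @param result A `simulation_result`.
#' @param time Requested time, s (the nearest stored snapshot is used).
#' @param field One of the snapshot fields, e.g. `"omega_nl"`, `"p_l"`,
#'   `"p_tl"`, `"p_t"`, `"u_s"`, `"S_t"`, `"omega_Nt"`, `"eps"`,
#'   `"omega_grow"`.
#' @param r Radii at which to sample (default: the snapshot nodes).
#' @return data.frame with columns `r` and `value` (attribute `"time"` gives
#'   the snapshot time actually used).
#' @export
probe_radial <- function(result, time, field, r = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  times <- vapply(result$snapshots, `[[`, numeric(1), "time")
  if (time < min(times) - 1e-9 || time > max(times) + 1e-9)
    stop("time outside the simulated range [", min(times), ", ",
         max(times), "] s", call. = FALSE)
  sn <- result$snapshots[[which.min(abs(times - time))]]
  ok <- setdiff(names(sn), c("time", "r"))
  if (!field %in% ok)
    stop("unknown field '", field, "'; available: ",
         paste(ok, collapse = ", "), call. = FALSE)
  if (is.null(r)) r <- sn$r
  out <- data.frame(r = r,
                    value = stats::approx(sn$r, sn[[field]], xout = r,
                                          rule = 2)$y)
  attr(out, "time") <- sn$time
  out
}

#' Thickness of the viable (proliferative) rim
#'
#' Radial extent of the region where the proliferative fraction is positive
#' (oxygen above the hypoxia threshold) inside the tumor front.
#'
#' @param result A `simulation_result`.
#' @param time Requested time, s.
#' @return Rim thickness, m.
#' @export
viable_rim <- function(result, time) {
  sn_om <- probe_radial(result, time, "omega_nl")
  sn_St <- probe_radial(result, time, "S_t")
  cl <- result$params$cell_line
  Rm <- .front_radius(sn_St$r, sn_St$value)
  inside <- sn_om$r <= Rm
  hypoxic <- inside & (sn_om$value <= cl$omega_crit)
  if (!any(hypoxic)) return(Rm)
  r_core <- max(sn_om$r[hypoxic])
  # refine the crossing by interpolation
  i <- max(which(hypoxic))
  if (i < nrow(sn_om)) {
    v1 <- sn_om$value[i]; v2 <- sn_om$value[i + 1]
    if (v2 > v1) {
      f <- (cl$omega_crit - v1) / (v2 - v1)
      r_core <- sn_om$r[i] + f * (sn_om$r[i + 1] - sn_om$r[i])
    }
  }
  max(Rm - r_core, 0)
}
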