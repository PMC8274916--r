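# Small, fast solver checks; the long-horizon physics runs live in
# test-acceptance.R. Shared miniature fixtures come from helper-configs.R.

test_that("radial mesh places interfaces exactly on nodes", {
  d <- domain_spec(R_seed = 80e-6, R_in = 100e-6, h = 34e-6,
                   R_domain = 300e-6)
  m <- build_mesh(d, discretization(dh = 5e-6))
  expect_true(any(abs(m$nodes - 100e-6) < 1e-15))
  expect_true(any(abs(m$nodes - 134e-6) < 1e-15))
  expect_true(all(diff(m$nodes) <= 5e-6 + 1e-12))
  expect_setequal(unique(m$subdomain), c("mcts", "alginate", "exterior"))
  # free growth: 300 um of domain at 5 um spacing gives 60 elements and
  # carries no shell tag
  mf <- build_mesh(domain_spec(R_seed = 50e-6, R_domain = 300e-6),
                   discretization(dh = 5e-6))
  expect_equal(mf$nelem, 60)
  expect_false("alginate" %in% mf$subdomain)
  expect_error(build_mesh(domain_spec(R_seed = 50e-6),
                          discretization(dh = 1)), "exceeds")
})

test_that("initial state encodes the seed and boundary conditions", {
  d <- domain_spec(R_seed = 50e-6, R_domain = 200e-6, S_t0 = 0.6)
  p <- model_parameters("CT26-optimized")
  st <- initialize_state(d, discretization(dh = 5e-6), p)
  ns <- st$mesh$ns
  expect_equal(st$om[ns], 4.2e-6)          # prescribed oxygen at the rim
  expect_equal(st$om[1], 4.2e-6)
  expect_equal(st$pl, rep(0, ns))
  # seed center saturation equals the prescribed S_t0 via the inverse of
  # the arctan closure
  expect_equal(cell_saturation(st$ptl[1], 0, p$cell_line$a), 0.6)
  # exterior carries no cell phase
  expect_equal(st$ptl[ns], 0)
  expect_equal(cell_saturation(st$ptl[ns], 0, p$cell_line$a), 0)
  expect_true(all(st$u == 0))
})

test_that("uniform quiescent state has zero residual", {
  d <- domain_spec(R_seed = 50e-6, R_domain = 200e-6, S_t0 = 0.6)
  p <- model_parameters(cell_line = cell_line_parameters(
    gamma_gt = 0, gamma_gnl = 0, gamma_0nl = 0, gamma_Nt = 0))
  st <- initialize_state(d, discretization(dh = 10e-6), p)
  st$ptl[] <- 0                       # no cells anywhere, no sources
  st$St_q[] <- 0
  st$eSlom_q <- st$eps_q * p$cell_line$omega_env
  r <- assemble_residual(st, st, 1200, p)
  expect_lt(max(abs(r)), 1e-12)
  # NaN in a field is reported by name
  st2 <- st
  st2$pl[3] <- NaN
  expect_error(assemble_residual(st2, st, 1200, p), "'pl'")
})

test_that("zero-source step leaves the state unchanged", {
  d <- domain_spec(R_seed = 50e-6, R_domain = 200e-6)
  p <- model_parameters(cell_line = cell_line_parameters(
    gamma_gt = 0, gamma_gnl = 0, gamma_0nl = 0, gamma_Nt = 0))
  disc <- discretization(dh = 10e-6, dt = 1200)
  st <- initialize_state(d, disc, p)
  st$ptl[] <- 0
  st$St_q[] <- 0
  st$eSlom_q <- st$eps_q * p$cell_line$omega_env
  st2 <- advance_step(st, disc, p)
  expect_lt(max(abs(st2$u)), 1e-12)
  expect_lt(max(abs(st2$pl)), 1e-9)
  expect_lt(max(abs(st2$om - st$om)), 1e-12)
})

test_that("pure diffusion relaxes oxygen to the boundary value", {
  d <- domain_spec(R_seed = 50e-6, R_domain = 150e-6)
  p <- model_parameters(cell_line = cell_line_parameters(
    gamma_gt = 0, gamma_gnl = 0, gamma_0nl = 0, gamma_Nt = 0))
  disc <- discretization(dh = 10e-6, dt = 600)
  st <- initialize_state(d, disc, p)
  st$ptl[] <- 0; st$St_q[] <- 0
  st$om[] <- 0.5 * p$cell_line$omega_env
  ns <- st$mesh$ns
  st$om[ns] <- p$cell_line$omega_env
  st$eSlom_q <- st$eps_q *
    (matrix(st$om[st$mesh$smap], st$mesh$nelem, 2) %*% t(st$mesh$N1))
  for (i in 1:10) st <- advance_step(st, disc, p)
  expect_lt(max(abs(st$om - p$cell_line$omega_env)),
            1e-3 * p$cell_line$omega_env)
})

test_that("anoxic necrosis follows its closed-form exponential", {
  d <- domain_spec(R_seed = 50e-6, R_domain = 150e-6)
  cl <- cell_line_parameters(gamma_gt = 0, gamma_gnl = 0, gamma_0nl = 0,
                             gamma_Nt = 0.01)
  p <- model_parameters(cl)
  disc <- discretization(dh = 10e-6, dt = 1200)
  st <- initialize_state(d, disc, p)
  st$om[] <- 0                          # full anoxia, boundary included
  st$om[st$mesh$ns] <- 0
  st$eSlom_q[] <- 0
  # oxygen frozen so the anoxic state persists; growth is off, so
  # d(omega_Nt)/dt = (gamma_Nt / rho_t) (1 - omega_Nt)
  nstep <- 30
  for (i in seq_len(nstep)) st <- advance_step(st, disc, p,
                                               active_om = FALSE)
  t_tot <- nstep * 1200
  expect_equal(max(st$omNt_q), 1 - exp(-cl$gamma_Nt / 1000 * t_tot),
               tolerance = 0.01)
  expect_equal(min(st$omNt_q), max(st$omNt_q), tolerance = 1e-6)
})

test_that("no growth means constant tumor volume", {
  d <- domain_spec(R_seed = 50e-6, R_domain = 150e-6)
  p <- model_parameters(cell_line = cell_line_parameters(
    gamma_gt = 0, gamma_gnl = 0, gamma_0nl = 0, gamma_Nt = 0))
  disc <- discretization(dh = 10e-6, dt = 2400, t_end = 12 * 2400,
                         snapshot_every = 1000)
  res <- run_simulation(d, disc, p)
  V <- res$series$V_tumor_m3
  expect_lt(max(abs(V - V[1])) / V[1], 5e-3)
})

test_that("radial probing interpolates stored snapshots", {
  # an essentially empty seed: no initial pressure, so the equilibrated
  # start has zero displacement
  d <- domain_spec(R_seed = 50e-6, R_domain = 150e-6, S_t0 = 1e-6)
  p <- model_parameters("generic")
  disc <- discretization(dh = 10e-6, dt = 2400, t_end = 4 * 2400,
                         snapshot_every = 2)
  res <- run_simulation(d, disc, p)
  pr <- probe_radial(res, 0, "omega_nl")
  expect_equal(pr$value, rep(4.2e-6, nrow(pr)), tolerance = 1e-6)
  pu <- probe_radial(res, 0, "u_s")
  expect_lt(max(abs(pu$value)), 1e-11)
  expect_error(probe_radial(res, 0, "bogus"), "available")
  expect_error(probe_radial(res, 1e9, "omega_nl"), "range")
})

test_that("halving dt changes the wall-pressure trajectory marginally", {
  d <- domain_spec(R_seed = 60e-6, R_in = 60e-6, h = 20e-6,
                   R_domain = 160e-6)
  p <- model_parameters("CT26-optimized")
  t_end <- 86400
  r1 <- run_simulation(d, discretization(dh = 10e-6, dt = 2400,
                                         t_end = t_end,
                                         snapshot_every = 1000), p)
  r2 <- run_simulation(d, discretization(dh = 10e-6, dt = 1200,
                                         t_end = t_end,
                                         snapshot_every = 1000), p)
  tq <- seq(0.25, 1, by = 0.25) * t_end
  p1 <- stats::approx(r1$series$time_s, r1$series$p_t_wall_Pa, tq)$y
  p2 <- stats::approx(r2$series$time_s, r2$series$p_t_wall_Pa, tq)$y
  expect_lt(max(abs(p1 - p2) / p2), 0.01)
})
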