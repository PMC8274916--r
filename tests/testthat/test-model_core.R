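test_that("oxygen growth switch has the piecewise cosine form", {
  wc <- 1e-6; we <- 4.2e-6
  expect_equal(growth_switch_H(we, wc, we), 1)
  expect_equal(growth_switch_H(2 * we, wc, we), 1)
  expect_equal(growth_switch_H(wc / 2, wc, we), 0)
  expect_equal(growth_switch_H((wc + we) / 2, wc, we), 0.5)
  expect_error(growth_switch_H(1e-6, we, wc), "omega_crit")
})

test_that("pressure switch is the linear ramp between the thresholds", {
  p1 <- 1432; pc <- 5944
  expect_equal(pressure_switch_Hp(p1, p1, pc), 0)
  expect_equal(pressure_switch_Hp(pc, p1, pc), 1)
  expect_equal(pressure_switch_Hp(3688, p1, pc), 0.5)
  expect_equal(pressure_switch_Hp(0, p1, pc), 0)
  expect_error(pressure_switch_Hp(0, pc, p1), "p1")
})

test_that("metabolism switch decays smoothly to zero oxygen", {
  we <- 4.2e-6
  expect_equal(metabolism_switch_Htilde(0, we), 0)
  expect_equal(metabolism_switch_Htilde(we, we), 1)
  expect_equal(metabolism_switch_Htilde(we / 2, we), 0.5)
  expect_error(metabolism_switch_Htilde(-1e-7, we), "non-negative")
})

test_that("switch functions are continuous, bounded and monotone", {
  wc <- 1e-6; we <- 4.2e-6
  w <- seq(0, 2 * we, length.out = 4001)
  for (f in list(function(x) growth_switch_H(x, wc, we),
                 function(x) metabolism_switch_Htilde(x, we),
                 function(x) pressure_switch_Hp(x * 2e9, 1432, 5944))) {
    y <- f(w)
    expect_true(all(y >= 0 & y <= 1))
    expect_true(all(diff(y) >= -1e-12))
    expect_lt(max(abs(diff(y))), 0.01)  # no jumps on a dense grid
  }
})

test_that("pressure-saturation closure matches its arctan form", {
  expect_equal(cell_saturation(0, 0, 890), 0)
  expect_equal(cell_saturation(890, 0, 890), 0.5)   # arctan(1) = pi/4
  expect_equal(cell_saturation(445, 0.5, 890), 0.5) # necrotic rescaling
  expect_equal(cell_saturation(-100, 0, 890), 0)    # no cells below zero
  expect_error(cell_saturation(100, 1, 890), "omega_Nt")
  expect_error(cell_saturation(100, 0, -1), "positive")
})

test_that("saturation increases with pressure difference and necrosis", {
  ptl <- seq(10, 5000, length.out = 60)
  for (wN in c(0, 0.3, 0.8)) {
    expect_true(all(diff(cell_saturation(ptl, wN, 890)) > 0))
  }
  for (p in c(100, 890, 3000)) {
    wN <- seq(0, 0.95, length.out = 40)
    expect_true(all(diff(cell_saturation(p, wN, 890)) > 0))
  }
})

test_that("fluid saturations and transport closures follow the power laws", {
  expect_equal(liquid_saturation(0), 1)
  expect_equal(liquid_saturation(1), 0)
  expect_equal(liquid_saturation(0.6), 0.4)
  D0 <- 3.2e-9
  expect_equal(oxygen_diffusivity(1, 1, D0, 2), D0)
  expect_equal(oxygen_diffusivity(0.5, 1, D0, 2), 0.25 * D0)
  expect_equal(oxygen_diffusivity(0.8, 0, D0, 2), 0)
  expect_error(oxygen_diffusivity(-0.1, 1, D0), "0, 1")
  k <- 1.8e-15
  expect_equal(hydraulic_conductivity(k, 1, 0.01, 2), k / 0.01)
  expect_equal(hydraulic_conductivity(k, 0, 0.01, 2), 0)
  expect_equal(hydraulic_conductivity(k, 0.5, 0.01, 2), 0.25 * k / 0.01)
  expect_error(hydraulic_conductivity(k, 1, 0, 2), "mu_f")
})

test_that("growth mass exchange is the product of its five factors", {
  cl <- cell_line_preset("CT26-optimized")
  # all switches at their extreme values
  expect_equal(growth_mass_exchange(cl$omega_env, cl$p1, 0, 0.8, 0.5, cl),
               3.33e-2 * 0.8 * 0.5, tolerance = 1e-12)
  expect_equal(growth_mass_exchange(cl$omega_crit / 2, 0, 0, 0.8, 0.5, cl),
               0)
  expect_equal(growth_mass_exchange(cl$omega_env, cl$p_crit, 0, 0.8, 0.5,
                                    cl), 0)
  # oracle: direct re-evaluation of the defining product on random draws
  set.seed(42)
  n <- 10000
  om <- runif(n, 0, 2 * cl$omega_env)
  pt <- runif(n, 0, 8000)
  wN <- runif(n, 0, 0.99)
  eps <- runif(n, 0.1, 0.95)
  St <- runif(n, 0, 1)
  direct <- cl$gamma_gt *
    growth_switch_H(om, cl$omega_crit, cl$omega_env) *
    (1 - pressure_switch_Hp(pt, cl$p1, cl$p_crit)) *
    (1 - wN) * eps * St
  expect_equal(growth_mass_exchange(om, pt, wN, eps, St, cl), direct)
})

test_that("oxygen sink keeps metabolism when growth is inhibited", {
  cl <- cell_line_preset("CT26-optimized")
  expect_equal(oxygen_sink(cl$omega_env, cl$p_crit, 0, 0.8, 0.5, cl),
               cl$gamma_0nl * 0.8 * 0.5)
  expect_equal(oxygen_sink(0, 0, 0, 0.8, 0.5, cl), 0)
  # eps * S_t = 0.4, both switches open
  cl2 <- cell_line_parameters(gamma_gnl = 4e-4, gamma_0nl = 6.65e-4,
                              p1 = 1432, p_crit = 5944, a = 890)
  expect_equal(oxygen_sink(cl2$omega_env, 0, 0, 0.8, 0.5, cl2),
               (4e-4 + 6.65e-4) * 0.4, tolerance = 1e-12)
})

test_that("necrosis rate vanishes at full oxygenation, peaks at anoxia", {
  cl <- cell_line_preset("generic")
  expect_equal(necrosis_rate(cl$omega_env, 0, 0.8, 0.5, cl$gamma_Nt,
                             cl$omega_env), 0)
  expect_equal(necrosis_rate(0, 0, 0.8, 0.5, cl$gamma_Nt, cl$omega_env),
               cl$gamma_Nt * 0.8 * 0.5)
  expect_equal(necrosis_rate(cl$omega_env / 2, 0.5, 0.8, 0.5, cl$gamma_Nt,
                             cl$omega_env),
               0.25 * cl$gamma_Nt * 0.8 * 0.5)
})

test_that("growing fraction is gated by hypoxia", {
  cl <- cell_line_preset("generic")
  expect_equal(growing_fraction(cl$omega_crit / 2, 0.7, cl), 0)
  expect_equal(growing_fraction(cl$omega_env, 0.7, cl), 0.7)
  expect_equal(growing_fraction(cl$omega_env / 2, 0.6, cl), 0.3)
})

test_that("effective stress applies the isotropic Voigt law", {
  E <- 1000; nu <- 0.4
  lm <- lame_constants(E, nu)
  expect_equal(effective_stress(matrix(0, 3, 3), E, nu), matrix(0, 3, 3))
  e <- 0.01
  s_uni <- effective_stress(diag(c(e, 0, 0)), E, nu)
  expect_equal(s_uni[1, 1], (lm$lambda + 2 * lm$mu) * e)
  expect_equal(s_uni[2, 2], lm$lambda * e)
  s_hyd <- effective_stress(e * diag(3), E, nu)
  expect_equal(s_hyd, (3 * lm$lambda + 2 * lm$mu) * e * diag(3) / 3 * 3)
  expect_error(effective_stress(diag(3) * 0.01, E, 0.5), "incompressible")
})

test_that("solid pressure is the saturation-weighted fluid pressure", {
  expect_equal(solid_pressure(1, 2000, 0), 2000)
  expect_equal(solid_pressure(0, 2000, -50), -50)
  expect_equal(solid_pressure(0.5, 2000, 0), 1000)
  # convex combination: bounded by the two fluid pressures
  set.seed(7)
  St <- runif(200); pt <- rnorm(200, 0, 2000); pl <- rnorm(200, 0, 50)
  ps <- solid_pressure(St, pt, pl)
  expect_true(all(ps >= pmin(pt, pl) - 1e-9 & ps <= pmax(pt, pl) + 1e-9))
})

test_that("porosity update conserves solid volume", {
  expect_equal(update_porosity(0.8, 1), 0.8)
  expect_equal(update_porosity(0.8, 1.25), 0.84)
  expect_equal(update_porosity(0.8, 1e9), 1, tolerance = 1e-8)
  expect_error(update_porosity(0.8, 0.19), "collapse")
})

test_that("parameter containers validate their invariants", {
  expect_error(cell_line_parameters(omega_crit = 5e-6, omega_env = 4.2e-6),
               "omega_crit")
  expect_error(cell_line_parameters(p1 = 5000, p_crit = 4000), "p_crit")
  expect_error(cell_line_parameters(gamma_gt = -1), "non-negative")
  expect_error(subdomain_material(E = 1000, nu = 0.5), "nu")
  opt <- cell_line_preset("CT26-optimized")
  expect_equal(opt$gamma_gt, 3.33e-2)
  expect_equal(opt$gamma_0nl, 6.65e-4)
  expect_equal(opt$a, 890)
  expect_equal(opt$p1, 1432)
  expect_equal(opt$p_crit, 5944)
  # "negligible" entries keep their generic values
  expect_equal(opt$mu_t, 36)
  expect_equal(opt$gamma_gnl, 4e-4)
})

test_that("model configuration round-trips through YAML and JSON", {
  p <- model_parameters("CT26-optimized")
  for (ext in c("yaml", "json")) {
    f <- file.path(tempdir(), paste0("cfg.", ext))
    write_model_config(p, f)
    q <- read_model_config(f)
    expect_equal(unclass(q$cell_line), unclass(p$cell_line))
    expect_equal(unclass(q$phases), unclass(p$phases))
  }
})
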