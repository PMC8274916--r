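# Miniature study configurations shared across test files. They reproduce
# the structure of the two training setups (free spheroid; encapsulated
# CCT0-like capsule, started with the lumen filled) at a desk-test scale:
# coarser mesh and time step, smaller capsule, 2-2.5 day horizons.

mini_free_domain <- function() domain_spec(R_seed = 50e-6,
                                           R_domain = 150e-6)

mini_free_disc <- function() discretization(dh = 10e-6, dt = 3600,
                                            t_end = 2.5 * 86400,
                                            snapshot_every = 1000)

mini_capsule_domain <- function()
  domain_spec(R_seed = 60e-6, R_in = 60e-6, h = 20e-6, R_domain = 160e-6)

mini_capsule_disc <- function() discretization(dh = 10e-6, dt = 3600,
                                               t_end = 2.4 * 86400,
                                               snapshot_every = 1000)

mini_free_runner <- function(cl)
  run_simulation(mini_free_domain(), mini_free_disc(), model_parameters(cl))

mini_capsule_runner <- function(cl)
  run_simulation(mini_capsule_domain(), mini_capsule_disc(),
                 model_parameters(cl))

# observation times of the miniature training data
mini_free_times <- function() c(0.5, 1, 1.5, 2, 2.5) * 86400
mini_conf_offsets <- function() c(0.5, 1, 2) * 86400

# free-volume series sampled from a forward run
mini_free_series <- function(sim, times = mini_free_times())
  data.frame(time_s = times,
             volume_m3 = stats::approx(sim$series$time_s,
                                       sim$series$V_tumor_m3, times)$y)

# capsule observations (wall displacement + solid pressure standing in for
# the confinement pressure) at offsets after confluence
mini_conf_series <- function(sim, offsets = mini_conf_offsets()) {
  s <- sim$series
  tc <- sim$confluence_time_s
  list(t_offset_s = offsets,
       u_Rin_m = stats::approx(s$time_s, s$R_in_m, tc + offsets)$y - 60e-6,
       P_conf_Pa = stats::approx(s$time_s, s$p_s_wall_Pa,
                                 tc + offsets)$y)
}

# named vector of the seven perturbation-study parameters
sensitivity_base <- function(cl = cell_line_preset("generic")) {
  pn <- c("mu_t", "a", "gamma_gt", "gamma_gnl", "gamma_0nl", "p1",
          "p_crit")
  vapply(pn, function(n) cl[[n]], numeric(1))
}

update_cell_line <- function(cl, p) {
  for (nm in names(p)) cl[[nm]] <- unname(p[nm])
  cl
}
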