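#' Concentric-subdomain geometry of a spheroid simulation
#'
#' Describes the three nested spatial regions sharing one physical model:
#' the MCTS interior, the (optional) alginate shell, and the exterior medium
#' with its mechanically negligible fictitious scaffold.
#'
#' @param R_seed Initial spheroid radius, m (where the cell phase starts).
#' @param R_in Capsule inner radius, m (encapsulated only).
#' @param h Shell thickness, m; `R_out = R_in + h`.
#' @param R_domain Outer boundary radius, m. Default: `2 (R_in + h)` when
#'   encapsulated, `4 R_seed` for free growth.
#' @param materials Named list of [subdomain_material()] for `mcts`,
#'   `alginate`, `exterior` (see [default_materials()]).
#' @param encapsulated Logical; `FALSE` simulates free growth (no shell).
#' @param S_t0 Initial tumor-cell saturation inside the seed.
#' @param transition_width Width over which the seed edge is smoothed, m.
#' @return Object of class `domain_spec`.
#' @export
domain_spec <- function(R_seed,
                        R_in = NULL, h = NULL,
                        R_domain = NULL,
                        materials = default_materials(),
                        encapsulated = !is.null(R_in),
                        S_t0 = 0.6,
                        transition_width = 5e-6) {
  stopifnot(R_seed > 0, S_t0 > 0, S_t0 < 1, transition_width > 0)
  if (encapsulated) {
    if (is.null(R_in) || is.null(h))
      stop("encapsulated domain needs R_in and h", call. = FALSE)
    R_out <- R_in + h
    if (!(R_seed <= R_in && R_in < R_out))
      stop("radii must satisfy R_seed <= R_in < R_out", call. = FALSE)
    if (is.null(R_domain)) R_domain <- 2 * R_out
    if (!(R_out < R_domain))
      stop("R_domain must exceed R_out", call. = FALSE)
  } else {
    R_in <- NULL; R_out <- NULL
    if (is.null(R_domain)) R_domain <- 4 * R_seed
    if (!(R_seed < R_domain))
      stop("R_domain must exceed R_seed", call. = FALSE)
  }
  stopifnot(all(c("mcts", "exterior") %in% names(materials)))
  if (encapsulated && !("alginate" %in% names(materials)))
    stop("encapsulated domain needs an 'alginate' material", call. = FALSE)
  structure(list(R_seed = R_seed, R_in = R_in, h = h, R_out = R_out,
                 R_domain = R_domain, materials = materials,
                 encapsulated = encapsulated, S_t0 = S_t0,
                 transition_width = transition_width),
            class = c("domain_spec", "list"))
}

#' Space-time discretization and solver controls
#'
#' Mixed elements use quadratic displacement and linear scalars (one order
#' apart, satisfying the inf-sup requirement in one dimension, with nodes
#' placed exactly on the subdomain interfaces).
#'
#' @param dh Target element size, m.
#' @param dt Base time step, s.
#' @param t_end Simulation horizon, s.
#' @param newton_tol Convergence tolerance on the scaled Newton increment.
#' @param newton_max Maximum Newton iterations per step.
#' @param max_dt_halvings Retry budget: how often a rejected step may halve dt.
#' @param geometry `"spherical"` (radial symmetry) or `"cartesian"`
#'   (consolidation-column kernel).
#' @param small_strain If `TRUE`, freeze geometry and porosity (linear
#'   poroelastic kernel, used for the consolidation benchmark).
#' @param c_reg Compressibility-like regularization (1/Pa) keeping the
#'   cell-phase equation well posed where the phase vanishes.
#' @param krel_floor Floor on the cell-phase relative permeability for the
#'   same reason.
#' @param D_floor Floor on the `eps S_l` argument of the oxygen diffusivity,
#'   keeping the oxygen equation non-degenerate in the packed necrotic core.
#' @param save_every Record scalar summaries every this many steps.
#' @param snapshot_every Store full radial field snapshots every this many
#'   steps (snapshots are always stored at the first and last step).
#' @return Object of class `discretization`.
#' @export
discretization <- function(dh = 5e-6, dt = 1200, t_end = 4 * 86400,
                           newton_tol = 1e-6, newton_max = 25,
                           max_dt_halvings = 10,
                           geometry = c("spherical", "cartesian"),
                           small_strain = FALSE,
                           c_reg = 1e-8, krel_floor = 1e-6, D_floor = 0.05,
                           save_every = 1L, snapshot_every = 10L) {
  geometry <- match.arg(geometry)
  stopifnot(dh > 0, dt > 0, t_end > 0, newton_tol > 0, newton_max >= 1)
  structure(list(dh = dh, dt = dt, t_end = t_end, newton_tol = newton_tol,
                 newton_max = newton_max, max_dt_halvings = max_dt_halvings,
                 geometry = geometry, small_strain = small_strain,
                 c_reg = c_reg, krel_floor = krel_floor, D_floor = D_floor,
                 save_every = as.integer(save_every),
                 snapshot_every = as.integer(snapshot_every)),
            class = c("discretization", "list"))
}

#' Build a conforming 1-D radial mesh with subdomain tags
#'
#' Nodes are placed exactly on the subdomain interfaces; within each segment
#' the element size is uniform and no larger than `dh`.
#'
#' @param domain A [domain_spec()].
#' @param disc A [discretization()].
#' @return Object of class `radial_mesh` with vertex coordinates, per-element
#'   subdomain tags, quadrature tables and the quadratic/linear dof maps.
#' @export
build_mesh <- function(domain, disc) {
  stopifnot(inherits(domain, "domain_spec"), inherits(disc, "discretization"))
  if (disc$dh > domain$R_domain)
    stop("element size dh exceeds the domain radius", call. = FALSE)
  if (domain$encapsulated) {
    brk <- c(0, domain$R_in, domain$R_out, domain$R_domain)
    tags <- c("mcts", "alginate", "exterior")
  } else {
    brk <- c(0, domain$R_seed, domain$R_domain)
    tags <- c("mcts", "exterior")
  }
  nodes <- numeric(0)
  subdom <- character(0)
  for (s in seq_along(tags)) {
    len <- brk[s + 1] - brk[s]
    ne <- max(1L, ceiling(len / disc$dh - 1e-9))
    xs <- seq(brk[s], brk[s + 1], length.out = ne + 1L)
    nodes <- c(nodes, xs[-length(xs)])
    subdom <- c(subdom, rep(tags[s], ne))
  }
  nodes <- c(nodes, brk[length(brk)])
  nelem <- length(nodes) - 1L
  # quadratic (displacement) and linear (scalar) dof maps
  umap <- cbind(2L * seq_len(nelem) - 1L, 2L * seq_len(nelem),
                2L * seq_len(nelem) + 1L)
  smap <- cbind(seq_len(nelem), seq_len(nelem) + 1L)
  # 3-point Gauss-Legendre on [-1, 1]
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5, 8, 5) / 9
  N1 <- cbind((1 - gp) / 2, (1 + gp) / 2)
  dN1 <- cbind(rep(-0.5, 3), rep(0.5, 3))
  N2 <- cbind(gp * (gp - 1) / 2, 1 - gp^2, gp * (gp + 1) / 2)
  dN2 <- cbind(gp - 0.5, -2 * gp, gp + 0.5)
  structure(list(nodes = nodes, nodes0 = nodes, nelem = nelem,
                 subdomain = subdom, umap = umap, smap = smap,
                 nu = 2L * nelem + 1L, ns = nelem + 1L,
                 gp = gp, gw = gw, N1 = N1, dN1 = dN1, N2 = N2, dN2 = dN2,
                 geometry = disc$geometry,
                 interface_in = if (domain$encapsulated)
                   which.min(abs(nodes - domain$R_in)) else NA_integer_,
                 interface_out = if (domain$encapsulated)
                   which.min(abs(nodes - domain$R_out)) else NA_integer_),
            class = c("radial_mesh", "list"))
}
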