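---
title: "A bio-chemo-poromechanical model of encapsulated tumor spheroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bio-chemo-poromechanical model of encapsulated tumor spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poroSpheroid)
```

## The physical picture

A multicellular tumor spheroid (MCTS) growing inside an elastic alginate
microcapsule is a three-phase porous medium: an extracellular-matrix (ECM)
scaffold, a tumor-cell (TC) "fluid" phase, and the interstitial fluid (IF)
carrying oxygen. The capsule is a thick-walled spherical shell whose
measured dilation reports, through elasticity, the pressure the spheroid
exerts on it — a biophysical dynamometer. `poroSpheroid` implements a
digital twin of this system: the coupled mass, momentum and oxygen
balances of the three phases on one continuous domain covering the capsule
lumen, the gel shell and the surrounding medium, plus the inverse analysis
that converts a capsule track back into pressures.

Three nested subdomains share one set of governing equations and differ
only in material constants: the MCTS interior (ECM scaffold, default
Young modulus 1 kPa), the alginate shell (68 ± 21 kPa as measured for
these capsules), and the exterior culture medium. The porous-media
framework requires a solid fraction everywhere, so the exterior carries a
fictitious scaffold of 0.6 kPa and porosity 0.99 — stiff enough to be
numerically sound and two orders softer than the gel, hence mechanically
negligible.

## Governing equations

Primary unknowns, all functions of radius and time:

* `u_s` — radial displacement of the solid scaffold (m),
* `p_l` — IF pressure (Pa),
* `p_tl` — TC/IF pressure difference (Pa),
* `omega_nl` — oxygen mass fraction in the IF (–);

with two internal variables per material point: the porosity `eps`
(updated from solid-mass conservation, `eps = 1 - (1 - eps0)/J`) and the
necrotic TC mass fraction `omega_Nt`.

The solved system is (i) the summed solid+fluid mass balance (all phases
incompressible, Biot coefficient 1), (ii) the TC-phase mass balance with a
Darcy flux and the growth source, (iii) oxygen advection–diffusion with
the consumption sink, and (iv) total momentum with the Biot effective
stress split `sigma_total = sigma_eff - p_s I`, where
`p_s = S_t p_t + S_l p_l` is the saturation-weighted solid pressure and
`sigma_eff` is linear-elastic in the scaffold strain.

Closure laws (all exported as plain functions, see `?cell_saturation`):

* saturation: `S_t = (2/pi) arctan(p_tl / ((1 - omega_Nt) a))` — the
  necrotic fraction thins the effective resistance, so necrotic regions
  pack more cells at the same pressure difference;
* relative permeability `S^A` with `A = 2` for both fluids;
* oxygen diffusivity `D0 (eps S_l)^2`, the exponent accounting for the
  tortuosity of the cell–cell interstitium;
* growth `gamma_gt H(omega)(1 - Hp(p_t))` on the living fraction, with a
  cosine oxygen ramp `H` between the hypoxia threshold `omega_crit` and
  the optimal fraction `omega_env`, and a linear pressure ramp `Hp`
  between `p1` and `p_crit`;
* oxygen consumption split into a growth-linked part (gated like growth)
  and a baseline metabolic part gated by the smoother switch `Htilde`;
* hypoxic necrosis at rate `gamma_Nt (1 - Htilde)` on the living
  fraction.

## Parameters

The cell-line presets mirror the two columns of the published CT26
parameter table: `"generic"` (literature initial guesses: growth rate
4e-2 kg/(m³·s), metabolic oxygen consumption 6e-4 kg/(m³·s), a = 800 Pa,
p1 = 1800 Pa, p_crit = 4000 Pa) and `"CT26-optimized"` (3.33e-2,
6.65e-4, 890, 1432, 5944 in the same order). The TC viscosity (36 Pa·s)
and growth-linked oxygen consumption (4e-4 kg/(m³·s)) are kept at their
generic values in both presets: the capsule data cannot identify them.

Parameters the study never printed are config entries with documented
defaults chosen once on physical grounds:

* intrinsic permeability `k = 1.8e-15 m²` (ECM-scale value used across
  this family of multiphase tumor models);
* IF viscosity `mu_l = 0.01 Pa·s`, so the Darcy mobility
  `k/mu_l = 1.8e-13 m²/(Pa·s)` sits at the permeable end of measured
  tumor-interstitium hydraulic conductivities; this choice reproduces
  IF-pressure excursions of a few Pa during encapsulated growth, the
  order reported for this experiment;
* free oxygen diffusivity `D0 = 3.2e-9 m²/s`; environmental oxygen mass
  fraction 4.2e-6 (90 mmHg by Henry's law), hypoxia threshold 1e-6;
* porosity 0.8 in the lumen and shell, 0.99 outside.

**Units of the necrosis rate.** Literature values for this coefficient
are quoted as 0.01 without explicit units. Read as 1/s it necroses all
tissue below optimal oxygen
within minutes, contradicting the day-scale necrotic-core development the
experiments and simulations show. Every other rate constant in the
parameter table is a mass rate in kg/(m³·s); `poroSpheroid` uses those
units for `gamma_Nt` too, giving a per-living-mass rate of
`gamma_Nt/rho_t = 1e-5 1/s` — a time scale of about a day under full
hypoxia, consistent with the published profiles.

## Discretization and solver

The fields depend on radius only, so the solver uses a one-dimensional
spherically symmetric mesh (weak forms weighted by `r²`), with a
Cartesian variant of the same kernel for the consolidation benchmark.
The spherical symmetry of the configuration makes this reduction exact
for the quantities of interest, at a small fraction of the cost of an
axisymmetric two-dimensional discretization; a 2-D backend would be an
extension point, not a requirement.

* Mixed elements: quadratic displacement, linear scalars (one order
  apart, the 1-D analogue of a Taylor–Hood pair), 3-point Gauss
  quadrature, nodes placed exactly on the lumen/shell/medium interfaces.
* Implicit Euler in time (base step 1200 s), monolithic Newton with line
  search; the Jacobian is built by finite differences with distance-2
  graph coloring (about fifteen residual evaluations per Jacobian) and
  row/column equilibration before the dense solve. A rejected step is
  retried with a halved step, composing sub-steps to cover the base step.
* Updated Lagrangian geometry: after each converged step the mesh moves
  with the solid, the deformation Jacobian accumulates multiplicatively,
  porosity follows solid-mass conservation, and stresses accumulate
  linear increments on the current configuration.
* Boundary conditions: symmetry at the center; at the outer radius
  `p_l = 0`, `p_tl = 0`, `omega_nl = 4.2e-6` and `u_s = 0`.

### Numerical safeguards and their rationale

* **Signed saturation closure.** The arctan law is evaluated with its
  sign in the residual. Clamping it to zero at `p_tl <= 0` makes the
  TC equation degenerate at the growth front and Newton fails there;
  the signed form keeps the system parabolic. Growth and consumption
  sources and the TC conductivity are floored at `S_t = 0`, so regions
  with `p_tl < 0` hold no cell mass and create none; reported
  saturations are clamped to `[0, 1)`. The small negative closure dip
  ahead of a traveling front is part of the discrete mass balance, so
  volume summaries integrate the signed field.
* **Shell cell-exclusion.** Lowering the shell's TC permeability (factor
  1e-6) is necessary but not sufficient in this discretization: the
  saturation closure is local, so pressure-difference values leaking one
  node into the shell would nucleate cells without transport. The shell
  therefore also scales the saturation parameter `a` by `a_factor = 1e6`
  — physically, the ~20 nm gel pores present an effectively infinite
  capillary entry pressure to cells. Shell saturations then stay below
  1e-5 in the reference run (the tested bound is 1e-3).
* **Residual mobilities.** The liquid relative permeability is floored
  at 1e-3 so the last IF can drain from a fully packed necrotic core,
  and the oxygen diffusivity argument `eps S_l` is floored at
  `D_floor = 0.05` — the smallest tested value restoring the discrete
  maximum principle (`0 <= omega <= omega_env`) — so the oxygen equation
  stays solvable where the IF fraction vanishes. Both floors act only in
  tissue that is already dead or cell-free.
* **Cell-phase regularization.** A compressibility-like term
  `c_reg = 1e-8 1/Pa` and a TC relative-permeability floor of 1e-6 keep
  the `p_tl` equation well posed in the cell-free exterior.
* **Mechanical pre-equilibration.** The initial state prescribes the
  seed's pressure difference but zero stress, which is far from
  mechanical equilibrium. Before time stepping, a displacement-only
  solve (scalars frozen) balances the initial solid pressure; without
  it the first step of a filled capsule needs extreme step cuts.

### Initial state

The seed starts at saturation `S_t0 = 0.6` (the aggregate is about 40%
IF at confluence) via `p_tl = a tan(pi S_t0 / 2)`, smoothed to zero over
a 5 µm transition — one element at the reference resolution, so the
cell front starts as sharp as the mesh can represent.
Encapsulated reference runs start with the lumen filled
(`R_seed = R_in`): the experimental capsule tracks and the published
analysis window both begin at confluence, and starting a traveling front
well inside the capsule would instead sample the front mid-profile at
the detected confluence time. Confluence is detected as the first time
the tumor front — the outermost radius where the nodal saturation
exceeds half its maximum — reaches the (current) inner-wall radius.
Inner-wall pressures are averaged over the two elements adjacent to the
wall, mirroring the thin integration subdomain of the original study.

## Verification

* **Terzaghi consolidation.** With one fluid, no growth and small
  strains, the kernel reduces to linear poroelasticity; a column loaded
  and drained at one face has the classical cosine-exponential series
  solution (`terzaghi_analytic`). The package compares
  solver profiles at dimensionless times 0.01–1 and reports the summed
  relative RMSE (Eq. form `sqrt(mean(((ex - num)/ex)^2))`); at the
  reference resolution (element 5 µm, dimensionless step 1e-4) the error
  is of the same order as the published value, and it decreases
  monotonically under refinement.
* **Mesh degradation.** Free-growth runs at element sizes 50–2.5 µm,
  monitoring the spheroid-center oxygen over four simulated days against
  the 2.5 µm reference, quantify the spatial error of the default 5 µm
  mesh. Linear scalar elements resolve the moving front less sharply
  than quadratic ones would, and that front-resolution error dominates
  this metric.
* **Time-step check.** Halving the base step changes the encapsulated
  wall-pressure trajectory by under one percent.

The test suite runs these at the stated resolutions; the miniature
configurations used for the calibration and sensitivity tests (10 µm
mesh, 1–3 day horizons, a 60 µm capsule) keep the whole suite at desk
scale while exercising the full physics.

## Sensitivity and calibration

The sensitivity machinery is the *local* response-surface variant, not
global Saltelli sampling, and the classes are named accordingly
(`local_sobol_result`). Seven parameters are perturbed one at a time on
a ±10% grid; the relative cost variation is fitted by a linear surface
and the squared slopes normalized into first-order indices. Pairwise
interaction indices come from evaluating the 21 parameter pairs at the
two diagonal grid extremes and fitting a second-order surface jointly
with the one-at-a-time runs. Two caveats are inherent to this design:
the diagonal-only pair evaluations cannot separate a pair coupling from
the parameters' own curvature, so strongly curved directions (the growth
rate, whose effect on volume is exponential) leak some curvature into
every pair they join; and indices are local to the baseline and the
surrogate data used.

The free-growth cost is the sum of squared volume mismatches at the data
days, the volume being the full-sphere integral of the cell volume
fraction. The confined cost compares the inner-wall displacement
(absolute mismatch by default; a squared dialect is available) and the
confinement pressure against the model displacement and solid pressure.
Because the two observables are tied through the shell elasticity, one
time point constrains only one combination of the two pressure
thresholds; identification therefore evaluates the cost on a short
series of post-confluence offsets (0.5, 1, 2 days), which separates
`p1` (whose influence peaks early) from `p_crit` (whose influence
grows). Both boundary terms are normalized by the boundary measure so
the mixed units (m and Pa²) keep comparable weight.

Calibration is bounded multi-start Nelder–Mead: candidates are clamped
to physical bounds with a quadratic penalty, the simplex tolerance is
made relative to the starting cost (SI volume costs are ~1e-23 m⁶ and
would otherwise sit below the optimizer's absolute floor), and the
staged protocol first fits (`gamma_gt`, `gamma_0nl`, `a`) on free-growth
volumes, then freezes them and fits (`p1`, `p_crit`) on the confined
observations with the mean alginate stiffness.

## The synthetic-experiment generator

`generate_synthetic_experiment()` runs the forward model at a stated
parameter set and samples either the free-growth volume series or the
capsule inner-radius track at stated times, with multiplicative Gaussian
noise (default 2% relative) under a fixed seed; the global RNG state is
left untouched. It emulates the *structure* of the study's training
curves — monotone pre-confluence volume growth; post-confluence capsule
strain rising and then saturating, with amplitude set by the alginate
stiffness — and is what the parameter-recovery and sensitivity tests
consume. It does not emulate biological replicate variability,
image-analysis noise correlations, or capsule-to-capsule geometry
scatter, so passing recovery tests demonstrate the identification
pipeline's correctness, not field performance on real microscopy data.

## Known limitations

* The published wall pressure at confluence is matched to within about
  ten percent, and the late-time pressure runs somewhat high with a
  correspondingly thinner viable rim: the linear scalar elements smear
  the saturation front over the wall-averaging band, where a quadratic
  scalar discretization would keep it sharp.
* The pre-confluence IF suction transient is largely absent in the
  filled-capsule protocol, which starts at confluence.
* Small strains per increment are assumed (updated Lagrangian); no
  contact mechanics between spheroid and shell beyond the continuous
  porous-media fields; a single nutrient; no cell-phenotype switching.
* The fit residuals and sensitivity percentages published for the real
  training curves cannot be recomputed without those curves; with
  surrogate data the package reproduces the qualitative ranking
  (growth rate dominant in free growth, critical pressure dominant under
  confinement, the saturation parameter–growth rate pair as the leading
  interaction).
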