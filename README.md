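# poroSpheroid

A bio-chemo-poromechanical digital twin of multicellular tumor spheroids
(MCTS) growing freely or confined inside elastic alginate microcapsules
(Cellular Capsule Technology). The capsule acts as a biophysical
dynamometer: its measured dilation reports, through thick-walled-shell
elasticity, the pressure the growing spheroid exerts. The package is for
computational biomechanics researchers who want to simulate these
experiments, interpret capsule tracks as phase pressures, and calibrate
cell-line parameters against growth data.

## The model

The spheroid–capsule system is one continuous reactive porous medium with
three phases — extracellular-matrix scaffold (s), tumor cells (t) and
interstitial fluid (l) — on three concentric subdomains (lumen, alginate
shell, culture medium). Four primary fields are solved monolithically:

* scaffold displacement u_s, with Biot effective stress
  σ_total = σ_eff − p_s I, p_s = S^t p^t + S^l p^l;
* IF pressure p_l and the cell/IF pressure difference p_tl = p_t − p_l,
  with Darcy fluxes k k_rel(S)/μ ∇p and the pressure–saturation closure
  S^t = (2/π) arctan( p_tl / ((1 − ω_Nt) a) );
* oxygen mass fraction ω_nl, with Fickian diffusivity D0 (ε S^l)^2 and a
  consumption sink split into growth-linked and metabolic parts.

Growth transfers mass from IF to cells at rate
γ_gt H(ω)(1 − Hp(p_t)) (1 − ω_Nt) ε S^t, gated by a cosine oxygen ramp H
between the hypoxia threshold and the optimal oxygen fraction and by a
linear pressure ramp Hp between p_1 and p_crit; prolonged hypoxia converts
living cells to a necrotic fraction ω_Nt. The solver is a 1-D
spherically-symmetric mixed finite-element kernel (quadratic displacement,
linear scalars, implicit Euler, monolithic Newton, updated-Lagrangian
geometry), verified against the closed-form Terzaghi consolidation series.
The CT26 cell-line parameter presets (`"generic"` and `"CT26-optimized"`)
ship with the package. See the vignette
`vignettes/poromechanics-of-encapsulated-spheroids.Rmd` for the full
model account, parameter table and numerical choices.

## Worked example

Simulate the reference encapsulated experiment (inner radius 100 µm,
shell 34 µm, alginate 68 kPa, optimized CT26 parameters) and compare the
model's wall pressures with what the shell inverse analysis would infer
from its own deformation:

```r
library(poroSpheroid)

domain <- domain_spec(R_seed = 100e-6, R_in = 100e-6, h = 34e-6,
                      materials = default_materials(E_alg = 68e3))
disc   <- discretization(dh = 5e-6, dt = 1200, t_end = 4.2 * 86400)
res    <- run_simulation(domain, disc, model_parameters("CT26-optimized"))

tc <- res$confluence_time_s
pt <- approx(res$series$time_s, res$series$p_t_wall_Pa,
             c(tc, tc + 85 * 3600))$y
cat(sprintf("confluence at %.2f h; wall p_t %.2f kPa -> %.2f kPa (+85 h)\n",
            tc / 3600, pt[1] / 1e3, pt[2] / 1e3))
#> confluence at 0.33 h; wall p_t 1.03 kPa -> 4.81 kPa (+85 h)

cmp <- compare_pressures(res, capsule_geometry(100e-6, h = 34e-6,
                                               E_alg = 68e3))
tail(round(cmp[, c("time_s", "P_conf_inverse", "p_s_model",
                   "p_t_model")]), 3)
```

The tumor-cell pressure at the moment of confluence is about 1 kPa and
rises toward 5 kPa over the following 85 hours as the capsule inflates;
the inverse-analysis confinement pressure tracks the *solid* pressure
p_s, which stays below p_t while the aggregate still holds interstitial
fluid — the package's central observation about what capsule dynamometry
actually measures.

A free-growth run is `run_simulation(domain_spec(R_seed = 50e-6), disc,
model_parameters("generic"))`; `generate_synthetic_experiment()` turns
either configuration into noisy observation series for calibration
studies, and `staged_identification()` recovers cell-line parameters from
them in two stages (growth/consumption/saturation on free data, then the
pressure thresholds on confined data).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/porospheroid.R simulate-capsule Rin=100e-6 h=34e-6 \
    Ealg=68e3 preset=CT26-optimized out=cct0.csv
Rscript inst/cli/porospheroid.R terzaghi-verify out=terzaghi.json
```

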