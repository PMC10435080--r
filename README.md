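# whiskerVT

Wake sensing with seal whisker arrays and an interpretable video
transformer.

Harbor seals can localize upstream objects purely from the hydrodynamic
wake those objects shed, read out as bending moments at the roots of their
whiskers. `whiskerVT` is a desk-scale, fully self-contained model of that
sensing chain for a canonical configuration: a circular plate (diameter
40 mm) in a 0.2 m/s freestream, 300 mm upstream of a two-sided array of
88 undulated whiskers. The package answers two questions: can the plate's
position and orientation — vertical offset X, lateral offset Y, yaw tilt
α, pitch tilt β — be regressed from the root-moment signals, and *which*
parts of the signal, in time and across the array, carry the information?

It is aimed at researchers in bioinspired flow sensing who want a
transparent, testable sandbox for array-signal decoding experiments
without a CFD cluster.

## The model

Four stages, each usable on its own:

1. **Geometry** — parametric undulated whiskers (elliptical cross-section
   with a 180° phase shift between the major- and minor-axis envelopes,
   linear taper), a mirror-symmetric 2 × 44 array, and the deterministic
   topological map onto the 9 × 22 sensing grid (110 null pixels).
2. **Wake** — a kinematic vortex-ring generator reproducing the documented
   plate-wake phenomenology: rings shed alternately from opposite plate
   edges every half period with a 180° phase difference; the wake
   translates rigidly with the plate and inclines with tilt; the far edge
   sheds the stronger ring; the Strouhal number
   `St = St0 (1 + c (sin²α + sin²β))` rises by up to 80% with tilt
   (`f = St U∞ / L'`, `L'` the hydraulic diameter of the projected frontal
   ellipse); at extreme single-axis tilt the wake degenerates to two
   steady streamwise vortex legs. Induced velocities are regularized
   Biot–Savart sums over ring filaments.
3. **Loads and signals** — the quasi-steady segment model
   `F_D, F_L = C_D, C_L · ½ ρ U² A_ref` with tabulated coefficients in
   local Reynolds number and angle of attack, reduced quasi-statically to
   body-fixed root moments (Mx′ from lift, My′ from drag); freestream
   baseline subtraction; DC/AC decomposition (slow/fast mechanoreceptor
   channels); assembly into the `80 × 9 × 22 × 4` sensing video.
4. **Decoder** — a factorized spatio-temporal video transformer written
   from scratch in R/C++: tubelet embedding, per-block spatial then
   temporal pre-LN multi-headed self-attention with residuals and a GELU
   MLP, mean pooling, and a regression head; Adam training with analytic
   backpropagation (finite-difference-checked); attention-rollout temporal
   (TI) and spatial (SI) importance maps.

## Worked example

A complete reduced study — 81-case parameter grid, signal synthesis,
training, prediction and interpretation:

```r
library(whiskerVT)

dp <- desk_protocol(seed = 1)          # grid, model and schedule
ds <- build_dataset(dp$grid)           # ~2 min: wake -> loads -> videos
fit <- wvt_fit(ds, dp$config, dp$control)   # ~40 s on one core
print(fit)
#> Video-transformer wake-sensing model
#>   tokens: 10 temporal x 6 spatial, G = 32, L = 2
#>   parameters: 62660
#>   final train MSE 0.06515
```

Predict a case and inspect what the network used:

```r
case <- which(ds$labels$X == 0 & ds$labels$Y == 200 &
              ds$labels$alpha == 0 & ds$labels$beta == 0)
predict(fit, ds)[case, ]
#>          X        Y   alpha      beta
#> 44 2.11082 191.5729 4.07064 -4.500174

imp <- importance(fit, ds, case = case)
print(imp)
#> Importance maps (rollout): TI over 10 temporal patches, SI 10 x 3 x 2
#> TI: 0.064 0.122 0.237 0.058 0.055 0.053 0.072 0.156 0.081 0.102
top_whiskers(imp, ds$grid_map, k = 5, patch = which.max(imp$TI))
#>   id row col        SI
#> 1 33   7  11 0.0122113
#> ...
```

The true plate sits fully to the right (Y = 200 mm); the fitted model
recovers the offsets and tilts to a few millimetres/degrees on the
training grid (in-sample accuracies 88.6 / 91.0 / 94.7 / 95.4% for X, Y,
alpha, beta against a 66.7% constant-mean baseline), and its temporal
importance peaks at the patches where the near-side vortex rings interact
with the array. `plot(fit)` shows the loss history; `summary(fit)`,
`residuals(fit)` and `wvt_cv()` give the fold-level view.

A thin command-line front end wraps the same pipeline:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/whiskervt.R", package="whiskerVT"))')" \
  simulate --grid 3,3,3,3 --seed 1 --out dataset.rds
```

with `train`, `interpret` and `report` subcommands writing checkpoints,
metrics CSVs and importance exports with content-hashed JSON manifests.

## Scope

The incompressible-flow and elastic-whisker solvers of cluster-scale
studies are intentionally out of scope: the wake is kinematic, loads are
quasi-static, whiskers are rigid. The methods vignette
(`vignettes/wake-sensing.Rmd`) documents every modelling choice, the
desk-scale study conditions, and what the synthetic-data results do and do
not demonstrate about real flows.
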