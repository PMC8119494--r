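# gaitWNN

Estimate sagittal ankle, knee and hip joint-angle profiles during walking
from **vertical ground reaction forces (vGRF) alone** — no body-mounted
kinematic sensors — using a two-layer **wavelet neural network (WNN)**.

Clinical gait analysis normally needs optical motion capture or multiple
inertial sensors strapped to the lower limb to measure joint kinematics.
Foot-mounted kinetic sensors (force plates, instrumented insoles) are far
less intrusive, but they measure load, not motion. This package implements
a regression pipeline that maps salient vGRF features of one normalized
gait cycle to the corresponding joint-angle profiles, for researchers in
biomechanics and wearable sensing who want kinematics estimates from
kinetics-only hardware.

## Method

**Gait-intervals (GI) feature selection.** Each gait cycle (initial contact
IC to next initial contact NIC) is normalized to a 0–100% phase grid. Nine
primary events — IC, OTO, HR, OIC, ITO, NTO, FA, TV, NIC — anchor the cycle
(measured toe-off/contact timings plus pre-defined normative indexes with a
±1% buffer). Thirteen intermediate events subdivide the seven sub-phases
(LR, MST, TST, PSW, ISW, MSW, TSW): a sub-phase bounded by events at
*t_start* and *t_end* with *n* intermediate events uses the step size

    b = (t_end − t_start) / (n + 1)

and places the k-th event at the grid point nearest *t_start + k·b*.
Coincident stance/swing transition events are split by ±1%, and any
remaining duplicate index is shifted +1% until unique. The result is 22
strictly increasing event indexes: features 1–11 sample the stance-leg vGRF
*f*, features 12–22 sample the opposite-leg vGRF *f′* (the swing foot
itself bears no load) multiplied by −1. Against a 100-point full-length
signal this is a 78% reduction in input dimensionality. Each cycle yields
22 inputs and 66 targets (ankle, knee, hip angles at all 22 events).

**Wavelet neural network.** Outputs combine a wavelon layer, a direct
linear path and a bias:

    ŷ_j = Σ_i ψ_i(x) ω_ij + Σ_k x_k ω_kj + b_j,
    ψ_i(x) = Π_k ψ((x_k − ω_(ξ)ki) / ω_(ς)ki),
    ψ(z) = (1 − z²) e^(−z²/2)   (Mexican hat)

Translations initialize to the per-input training range midpoint,
dilations proportionally to the range, biases to the target means. The
cost L = (1/N) Σ_p ‖y_p − ŷ_p‖² is minimized by full-batch gradient
descent with momentum (defaults: 5 hidden nodes chosen by minimum
prediction risk, 50 epochs, cost floor 1e-5). A budget-matched sigmoid
MLP baseline is included. Predicted 22-point angle sets are expanded to
full 101-point profiles by cubic spline interpolation and scored with
RMSE (°), range-normalized RMSE (%) and Pearson ρ, over all samples and
separately in-sample/out-sample for three independent 70/30 splits.

Because the original motion-capture cohort is not deposited, the package
ships a synthetic gait generator (`generate_cohort()`) producing paired
kinetic/kinematic cycles — double-bump stance vGRF, half-cycle-offset
contralateral signal, normative Fourier angle templates, subject- and
trial-level variability — whose shared latent parameters guarantee a
learnable vGRF→angle mapping.

## Worked example

```r
library(gaitWNN)
cohort <- generate_cohort(n_subjects = 30, trials_per_subject = 10, seed = 1)
report <- run_experiment(cohort, training_config(E_max = 50, n_hidden = 5,
                                                 seed = 17))
print(report)
```

```
Joint-angle estimation report

WNN (chosen sequence 2, least mean RMSE):
  all        ankle 0.66+/-0.36 deg (NRMSE 3.0%, rho 0.993); knee 1.83+/-1.07 deg (NRMSE 3.1%, rho 0.994); hip 0.81+/-0.44 deg (NRMSE 2.2%, rho 0.998)
  in_sample  ankle 0.65+/-0.35 deg (NRMSE 2.9%, rho 0.994); knee 1.79+/-1.06 deg (NRMSE 3.0%, rho 0.994); hip 0.80+/-0.43 deg (NRMSE 2.2%, rho 0.998)
  out_sample ankle 0.70+/-0.37 deg (NRMSE 3.2%, rho 0.993); knee 1.93+/-1.09 deg (NRMSE 3.3%, rho 0.993); hip 0.85+/-0.46 deg (NRMSE 2.3%, rho 0.997)

MLP (chosen sequence 2, least mean RMSE):
  all        ankle 0.67+/-0.36 deg (NRMSE 3.0%, rho 0.993); knee 1.86+/-1.08 deg (NRMSE 3.2%, rho 0.994); hip 0.82+/-0.44 deg (NRMSE 2.3%, rho 0.998)
  ...
```

Reading the report: each line gives mean ± SD across the scored samples of
the per-profile RMSE in degrees, the RMSE as a percent of the ground-truth
angle range (NRMSE), and the mean Pearson correlation between estimated
and true 101-point profiles. "all" pools training and held-out samples;
"in_sample"/"out_sample" separate them — their agreement (here within
0.1°) is the generalization check. The chosen sequence is the 70/30
shuffle with the least mean RMSE. On this synthetic cohort both models
converge well within the 5-node/50-epoch budget; on harder, noisier
mappings the wavelon layer's localized activations are what separate the
WNN from the sigmoid baseline.

A command-line wrapper with `simulate | features | train | evaluate |
run-all` subcommands is installed at `inst/cli/gaitwnn.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gaitwnn.R", package="gaitWNN"))')" \
    run-all --out runs/demo --seed 1
```

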