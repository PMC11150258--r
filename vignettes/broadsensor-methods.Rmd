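---
title: "Methods: adaptive broad-learning soft sensors for batch bioprocesses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive broad-learning soft sensors for batch bioprocesses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Fed-batch fermentations are strongly nonlinear, vary from batch to batch,
and their key quality variable — here penicillin concentration — is hard to
measure online. A *soft sensor* predicts that variable from the easily
measured process variables (flows, temperatures, off-gas, pH, dissolved
oxygen, ...). Two features of batch processes make this hard: the
input-output relation is nonlinear, and it drifts over time (equipment
aging, raw-material changes, deliberate recipe variation). `broadsensor`
implements a family of fast closed-form learners for the first problem and
a moving-window stacking ensemble for the second, together with a
self-contained mechanistic fermentation simulator used to generate all
experimental data.

# The estimators

All three estimators share the *broad learning system* (BLS) skeleton.
Inputs are standardized, then mapped through a random feature layer of
`n_groups` groups of `nodes_per_group` nodes,

  Z_i = phi(X W_i + b_i),   W_i, b_i ~ Uniform[-1, 1],  phi = tanh,

with Z the column concatenation of the groups (n_F columns in total). The
hidden layer is `A = [Z, B]` where the block `B` distinguishes the modes:

* **bls** — a second random map ("enhancement nodes"),
  `B = tanh(Z W_h + b_h)`.
* **kbls** — the exact Gaussian-kernel Gram matrix of the feature nodes,
  `B = K`, `K[i,j] = exp(-||z_i - z_j||^2 / (2 sigma^2))`.
* **akbls** — a random-Fourier-feature (RFF) approximation of that Gram
  matrix. `m_fourier` frequency vectors are drawn from N(0, sigma^-2 I) —
  the spectral density of the Gaussian kernel — giving the 2m-dimensional
  map `z(x) = m^-1/2 (cos(w_j'x), sin(w_j'x))_j` whose inner products
  estimate the kernel. `B = Omega = H H'` with `H` the mapped feature
  nodes. The estimate is unbiased and its error decays as m^-1/2, which
  the test suite checks against the exact Gram.

The output weights solve the ridge problem `argmin ||A W - y||^2 +
gamma ||W||^2` in closed form; the package uses whichever of the two
algebraically identical solutions (`A'(gamma I + A A')^{-1} y` or
`(gamma I + A'A)^{-1} A'y`, equal by the push-through identity) factors the
smaller Gram matrix. At `gamma = 0` a minimum-norm SVD pseudo-inverse is
used. The printed form of the regularized pseudo-inverse in the source
material is dimensionally inconsistent (it right-multiplies by `A'` where
only a left factor can close the dimensions); the implementation uses the
consistent ridge form, which reduces to the same limit.

A kernel autoencoder links the feature nodes to the kernel block:
`W_Omega = argmin ||Z W - Omega||^2 + C ||W||^2`, solved the same way. Its
single ridge constant `C` plays the role of both regularization constants
that appear around the autoencoder in the source material, which are the
same quantity written twice.

## Prediction-time kernel columns: a deliberate deviation

For a new sample, the kernel block columns can be built two ways: the
cross-Gram of the new sample against the stored training features
(`test_kernel = "direct"`), or the autoencoder reconstruction
`Omega* = Z* W_Omega` (`test_kernel = "ae"`). The reconstruction is
*linear* in the feature layer, so under `"ae"` the whole model collapses to
a linear predictor on n_F random features: the kernel block contributes no
test-time capacity, the training fit is not reproduced on the training
inputs even as `gamma -> 0`, and a target as simple as `sin(3 x1) + x2^2`
cannot be recovered. The package therefore defaults to `"direct"` and keeps
`"ae"` as an ablation switch. This is a deviation from the design this
package was first sketched with, made because the implementation
demonstrates the alternative cannot satisfy the model's own contracts.

## Defaults and the parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `n_groups`, `nodes_per_group` | 10, 10 | 100 feature nodes; the main capacity dial, searched by CV in the packaged experiments (10-30 nodes per group) |
| `m_fourier` | 500 | Fourier components; kernel approximation error ~ m^-1/2 |
| `sigma` | median heuristic | median pairwise distance of the training feature nodes, a standard scale-free bandwidth; `sigma_scale` multiplies it |
| `C` | 1e-6 | autoencoder ridge; only conditions a reconstruction, small is safe |
| `gamma` | 1e-6 | output ridge; near-interpolation on noise-free data |
| `n_enhance` | 100 | bls enhancement nodes |

# Stacking ensemble

Three AKBLS primary learners are derived from one (typically CV-tuned) base
configuration: distinct seeds plus a +/-25% perturbation of
nodes-per-group, Fourier components and bandwidth scale, so their errors
decorrelate. Their out-of-fold predictions under a k-fold split (k = 5,
contiguous-in-time blocks by default because process data is serially
correlated; a shuffle switch exists) form an N x 3 meta-feature table with
no self-fold leakage, which the tests assert on the fold bookkeeping. The
bases are then refit on the full window.

The meta-learner is a Gaussian process regression with an explicit linear
mean (universal kriging) and a squared-exponential covariance, fit on the
meta table with hyperparameters by marginal likelihood. Three numerical
choices matter and were made once, for reasons the degenerate cases make
visible:

* **Linear mean.** A zero-mean GP reverts to the sample mean away from its
  training cloud. Refit bases shift slightly relative to the out-of-fold
  meta-features, so test points often sit at the cloud's edge; with a
  linear mean the predictor degrades to a linear blend there instead of
  collapsing toward the average target.
* **Length-scale floor (1) and signal-variance cap (1), standardized
  units.** Near-interpolating bases leave tiny but *systematic*
  out-of-fold residuals; unconstrained maximum likelihood fits them with a
  collapsed length-scale and a huge signal variance — corrections that do
  not transfer to the refit bases and can destroy the prediction under
  mild drift.
* **Noise floor (0.1 sd).** Treating meta-features as at least 10% noisy
  stops the GP from reproducing fold-specific miscalibration; with three
  identical bases the ensemble then deviates from the single base by well
  under 2% of the target's spread, which is the behaviour a degenerate
  ensemble must have.

For windows larger than 400 rows the GP is fit on a seeded 400-point
subsample of the meta table: the meta space is 3-dimensional, so the cap
costs little accuracy and bounds the O(N^3) cost. A plain linear
meta-learner is available (`meta = "linear"`) and is the automatic fallback
if the GP optimizer fails.

# Moving-window adaptation

The training database is time-ordered. Window `m` covers rows
`[m*l, m*l + w_m]` — a closed interval, hence `w_m + 1` rows; the off-by-one
is implemented literally as specified and is immaterial at the scales used.
Each iteration fits a stacking ensemble on the current window, predicts the
next `l` test rows, appends feedback rows to the database (by default the
model's *own predictions*, matching self-labelled online operation; true
labels and no feedback are options — the choice changes the semantics and
is logged in every report), and advances the window by `l`. A final partial
chunk is predicted with the last model. The number of fitted windows is
floor(test size / l) and every test row is predicted exactly once.

Defaults `w_m = 2400`, `l = 100`: with hourly sampling and 400 h batches
the window then spans six complete batches. The window must contain several
whole batches — the hardest region to generalize across batches is the
transition around feed start, and a window holding only one or two batches
leaves the ensemble extrapolating there. `l = 100` retrains four times per
400 h test batch, a refresh rate comparable to common practice of
re-identifying a batch model a few times per run.

# The fermentation simulator

`fermsim`-style data is produced by a Birol-type mechanistic model of
fed-batch penicillin fermentation: Contois-limited growth with oxygen
limitation, non-growth-associated product formation with substrate
inhibition and first-order hydrolysis, substrate maintenance, fed-batch
dilution, and heat/CO2/pH/temperature outputs under proportional control.
States are integrated with a fixed-step 4th-order Runge-Kutta scheme
(default 0.1 h; halving the step changes the hourly product trajectory by
~1e-7 relative, far inside the 0.1% convergence contract) and sampled
hourly. Dissolved oxygen is treated as quasi-steady — its time constant,
1/kla, is minutes against the hourly grid — which removes the only stiff
mode from the ODE system; the quasi-steady value is solved by damped fixed
point at every stage evaluation.

Kinetic parameter values follow the published Birol-family model (e.g.
maximum specific growth rate 0.092 1/h, Contois constant 0.15 g/g,
specific production rate 0.005 1/h, substrate inhibition 0.1 g/L, yields
0.45 and 0.90 g/g, hydrolysis 0.04 1/h). The default batch: 15 g/L initial
substrate, 0.1 g/L inoculum, 100 L, 400 h, with feeding (0.042 L/h of
600 g/L substrate) ramping in at 44 h, just before the batch phase
exhausts the initial substrate. Product rises smoothly to about 1.4 g/L.

The 15 measured variables are: air flow, agitator power, feed flow, acid
flow, base flow, cooling water flow, hot water flow, substrate
concentration, dissolved oxygen, biomass concentration, culture volume,
off-gas CO2, pH, temperature and cumulative heat. Actuator flows come from
simple proportional controllers; they are smooth, mildly varying and
correlated with the metabolic state, which is what the soft-sensor models
need. Campaigns draw initial substrate, biomass and volume uniformly
within +/-10%, +/-10% and +/-5% of the base values (a realistic
inoculum/charge variability for a production campaign); a one-batch
campaign is the base batch itself. Measurement noise is optional
independent Gaussian noise per column, specified as per-variable SDs or as
a signal-to-noise ratio (the packaged "noise treatment" preset uses
40 dB), with non-negative variables clipped at zero and the target left
clean unless asked otherwise.

What the generator does *not* emulate: sensor drift and calibration error,
missing data, fault scenarios, correlated (colored) noise, discrete lab
assays with delay, or any closed-loop dependence of the recipe on the
model. A green test therefore establishes that the estimators and the
adaptive machinery work on smooth, well-behaved multi-batch data of the
stated dimensionality and drift pattern — not that they survive raw plant
historians.

# Experiment presets and reported scales

`run_experiment()` packages three designs: the estimator comparison across
dataset sizes (80/20 split, 5-fold-CV-tuned, mean of ten reseeded fits),
the 12-cell framework ablation ({plain, moving window, stacking, both} x
{bls, kbls, akbls}) on a drifting campaign, and the headline multi-batch
moving-window run with noise-treated training data. Reported RMSE is on
the standardized-target scale by default (raw-unit values are also
returned), because that is the only scale on which error magnitudes are
comparable across datasets; every report embeds the resolved configuration
and all seeds. Training-time measurements are logged for information only
— they are hardware-dependent and no acceptance claim rests on them.

In the ablation, the "plain" and "stacking" (non-moving) models are
trained on the most recent window-sized slice of the training database, so
all four frameworks see the same training budget and the comparison
isolates adaptation and ensembling rather than training-set size. The
ablation feeds back true labels (delayed-assay semantics); the headline
run feeds back predictions (self-labelled online semantics).

# Known limitations

* The GP meta-learner is deliberately conservative; on problems where base
  errors are large and structured, a freer meta-learner could do better.
* The moving window indexes from the start of the database as specified;
  with a long pre-existing database and no feedback, the window can lag
  far behind the newest data. Feeding back with `l`-sized steps keeps the
  window anchored to the stream (the configuration used everywhere here).
* The simulator's pH/temperature loops are simple proportional
  controllers, not the cascade controllers of a real plant; the actuator
  columns are smoother than real ones.
* Kernel modes store their training features; memory grows with the
  window, which is why the window length, not the database, bounds the
  model size.
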