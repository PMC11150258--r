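# broadsensor

Adaptive soft sensors for batch bioprocesses, built on the broad learning
system (BLS) family of closed-form neural networks.

## What it is for

In fed-batch fermentation the product concentration (here penicillin, g/L)
is hard to measure online, while flows, temperatures, pH, dissolved oxygen
and off-gas are cheap. A soft sensor learns the map from those 15 measured
process variables to the product concentration. Batch processes are
nonlinear and drift between batches, so the package combines:

* **BLS / KBLS / AKBLS** — flat networks whose output layer is solved in
  closed form by ridge regression. BLS uses random enhancement nodes; KBLS
  replaces them with an exact Gaussian-kernel Gram block; AKBLS
  approximates that block with random Fourier features (RFF), cutting the
  kernel cost while keeping its accuracy (`fit_model()`, `predict()`).
* **Stacking** — three AKBLS primary learners with decorrelated
  configurations, combined by a Gaussian-process meta-learner fit on
  out-of-fold predictions (`fit_stacking()`).
* **Moving window** — the ensemble is retrained on a fixed-length window
  that slides through the time-ordered database as new samples arrive,
  tracking process drift (`run_mw_stacking()`).
* **fermsim** — a self-contained Birol-style fed-batch penicillin
  simulator (Contois growth, substrate-inhibited production, fed-batch
  dilution, proportional pH/temperature control; RK4 integration, hourly
  sampling) that generates all experimental data: single batches,
  multi-batch campaigns with varied initial conditions, measurement noise
  (`simulate_batch()`, `simulate_campaign()`, `fermsim_preset()`).

In notation: feature nodes `Z_i = phi(X W_i + b_i)`; kernel block
`Omega = H H'` with `H` the RFF map of `Z`; hidden layer `A = [Z, Omega]`;
output weights `W = A'(gamma I + A A')^{-1} y`. Metrics are R² and RMSE.

## Worked example

```r
library(broadsensor)

# 800-sample penicillin dataset (two 400 h batches, 15 variables)
data  <- fermsim_preset("table3_1", seed = 1)
split <- train_test_split(data, 0.8, seed = 1)

model <- fit_model(split$train, model_config("akbls", nodes_per_group = 20))
pred  <- predict(model, split$test$X)
r2_score(split$test$y, pred)
#> [1] 0.9999908
```

An R² of 0.99999 on the held-out 20%: on noise-free simulated data the
approximate-kernel model reproduces the product concentration almost
exactly. The adaptive driver on a 20-batch campaign:

```r
camp <- fermsim_preset("campaign20", seed = 0)
tune <- cv_grid_search(camp$train[1:801], "akbls",
                       list(nodes_per_group = c(10, 20, 30),
                            sigma_scale = c(1, 2), gamma = c(1e-8, 1e-6)))
run  <- run_mw_stacking(camp$train, camp$test,
                        cfg = stack_config(base = tune$best_config, seed = 0))
run$overall$r2
#> [1] 0.9999306
```

Command-line entry points (wrapper scripts in `inst/cli/`, installed next
to the package; `fermsim_cli()` / `softsensor_cli()` expose the same
interface from R):

```sh
Rscript inst/cli/fermsim.R simulate --batches 20 --seed 1 --out campaign.csv
Rscript inst/cli/softsensor.R train --model akbls --train train.csv --save model.json
Rscript inst/cli/softsensor.R predict --load model.json --in test.csv --out pred.csv
Rscript inst/cli/softsensor.R mw-run --train train.csv --test test.csv \
        --window 2400 --step 100 --out pred.csv --report report.json
```

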