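# Fermentation simulator: trivial contracts, determinism, conservation and
# step-size convergence.

test_that("no biomass and no feed means no product, ever", {
  cfg <- batch_config(biomass0 = 0, feed_rate = 0, duration_h = 50)
  d <- simulate_batch(cfg)
  expect_equal(d$y, rep(0, 50))
  expect_equal(unname(d$X[, "biomass_conc"]), rep(0, 50))
})

test_that("simulation is deterministic and noise is seed-reproducible", {
  cfg <- batch_config(duration_h = 60)
  expect_identical(simulate_batch(cfg), simulate_batch(cfg))
  cfgn <- batch_config(duration_h = 60, noise = list(snr_db = 40), seed = 7)
  expect_identical(simulate_batch(cfgn), simulate_batch(cfgn))
  cfgn2 <- cfgn; cfgn2$seed <- 8
  expect_false(identical(simulate_batch(cfgn)$X, simulate_batch(cfgn2)$X))
})

test_that("halving the integration step changes the product trajectory < 0.1%", {
  d1 <- simulate_batch(batch_config())                 # default dt
  d2 <- simulate_batch(batch_config(dt_h = 0.05))      # halved
  denom <- pmax(abs(d2$y), 1e-3 * max(d2$y))
  expect_lt(max(abs(d1$y - d2$y) / denom), 1e-3)
})

test_that("trajectories are non-negative and volume balance closes", {
  d <- short_batch()
  nn <- intersect(colnames(d$X),
                  c("substrate_conc", "dissolved_oxygen", "biomass_conc",
                    "culture_volume", "heat_generated"))
  expect_true(all(d$X[, nn] >= 0))
  expect_true(all(d$y >= 0))
  vb <- attr(d, "volume_balance")
  expect_equal(vb[["dV"]], vb[["net_fed"]], tolerance = 1e-9)
})

test_that("campaign draws distinct batches within the stated ranges", {
  camp <- simulate_campaign(20, batch_config(duration_h = 30), seed = 3)
  expect_length(unique(camp$batch_id), 20)
  ini <- attr(camp, "initials")
  expect_true(all(ini$substrate0 >= 15 * 0.9 & ini$substrate0 <= 15 * 1.1))
  expect_true(all(ini$biomass0 >= 0.1 * 0.9 & ini$biomass0 <= 0.1 * 1.1))
  expect_true(all(ini$volume0 >= 100 * 0.95 & ini$volume0 <= 100 * 1.05))
})

test_that("degenerate campaigns behave as documented", {
  base <- batch_config(duration_h = 40)
  one <- simulate_campaign(1, base, seed = 5)
  ref <- simulate_batch(base, batch_id = "batch_01")
  expect_equal(one$X, ref$X)
  expect_equal(one$y, ref$y)
  expect_warning(
    two <- simulate_campaign(2, base, variation = c(substrate = 0),
                             seed = 5),
    "zero variation")
  expect_equal(two$X[1:40, ], two$X[41:80, ])
})

test_that("measurement noise has the requested magnitude and clips at zero", {
  set.seed(1)
  X <- matrix(abs(rnorm(1e4, 5)), ncol = 1, dimnames = list(NULL, "v1"))
  d <- process_dataset(X, rowSums(X))
  noisy <- add_measurement_noise(d, c(v1 = 0.1), seed = 2)
  expect_true(stats::sd(noisy$X - d$X) > 0.09 && stats::sd(noisy$X - d$X) < 0.11)
  expect_identical(add_measurement_noise(d, c(v1 = 0))$X, d$X)
  dz <- process_dataset(matrix(0, 500, 1, dimnames = list(NULL, "v1")),
                        rep(1, 500))
  expect_true(all(add_measurement_noise(dz, c(v1 = 1), seed = 3)$X >= 0))
  expect_error(add_measurement_noise(d, c(nope = 1)), "unknown variable")
  # input is not modified in place
  before <- d$X
  invisible(add_measurement_noise(d, c(v1 = 1), seed = 4))
  expect_identical(d$X, before)
})

test_that("config validation rejects impossible setups", {
  expect_error(batch_config(duration_h = -1), "duration")
  expect_error(batch_config(dt_h = 2, sample_period_h = 1), "integration step")
  expect_error(batch_config(dt_h = 0.3), "divide")
  expect_error(batch_config(volume0 = 0), "volume")
  expect_error(batch_config(feed_profile = data.frame(time = 0, rate = -1)),
               "negative feed")
})

test_that("CSV round-trip preserves the table at 6 significant digits", {
  d <- short_batch()
  f <- withr::local_tempfile(fileext = ".csv")
  write_process_csv(d, f)
  txt <- readLines(f)
  expect_equal(txt[1],
               paste(c(penicillin_variables(), "target", "batch_id"),
                     collapse = ","))
  back <- read_process_csv(f)
  expect_equal(back$X, d$X, tolerance = 1e-5)
  expect_equal(back$y, d$y, tolerance = 1e-5)
  expect_identical(back$batch_id, d$batch_id)
})

test_that("dataset presets deliver the advertised sizes", {
  d <- cached("preset800", fermsim_preset("table3_1", seed = 1))
  expect_equal(nrow(d$X), 800)
  expect_equal(ncol(d$X), 15)
  expect_identical(colnames(d$X), penicillin_variables())
  expect_error(fermsim_preset("nope"), "unknown preset")
})
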