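# Fed-batch penicillin fermentation simulator.
#
# A Birol-style mechanistic model: Contois growth with substrate and oxygen
# limitation, non-growth-associated penicillin formation with substrate
# inhibition and hydrolysis, fed-batch dilution, dissolved-oxygen transfer,
# and algebraic actuator/off-gas outputs under simple proportional pH and
# temperature control. States are integrated with a fixed-step classical
# 4th-order Runge-Kutta scheme and subsampled to the (hourly) sampling grid.

#' Default variable names of a simulated penicillin dataset
#'
#' The fifteen measured process variables of the fed-batch penicillin
#' process, in canonical order. The prediction target (penicillin
#' concentration, g/L) is stored separately.
#'
#' @return character vector of length 15.
#' @export
penicillin_variables <- function() {
  c("air_flow", "agitator_power", "feed_flow", "acid_flow", "base_flow",
    "cooling_water_flow", "hot_water_flow", "substrate_conc",
    "dissolved_oxygen", "biomass_conc", "culture_volume", "co2_conc",
    "ph", "temperature", "heat_generated")
}

# Variables constrained to be non-negative (everything except pH and
# temperature, which live on absolute scales).
nonneg_variables <- function() {
  setdiff(penicillin_variables(), c("ph", "temperature"))
}

#' Kinetic parameters of the penicillin fermentation model
#'
#' Parameter set of the fed-batch penicillin kinetics (Contois-limited
#' growth, substrate-inhibited product formation, oxygen uptake, CO2
#' evolution and metabolic heat). Defaults follow the published Birol-type
#' fermentation model commonly used for penicillin process simulators.
#'
#' @param mu_x maximum specific growth rate (1/h).
#' @param K_x Contois substrate saturation constant (g substrate / g biomass).
#' @param mu_p specific product formation rate constant (1/h).
#' @param K_p product formation saturation constant (g/L).
#' @param K_I substrate inhibition constant for product formation (g/L).
#' @param K_ox,K_op oxygen limitation constants for growth and production.
#' @param Y_xs,Y_ps yields: biomass and product per substrate (g/g).
#' @param Y_xo,Y_po yields: biomass and product per oxygen (g/g).
#' @param m_x maintenance coefficient on substrate (1/h).
#' @param m_o maintenance coefficient on oxygen (1/h).
#' @param K_h penicillin hydrolysis rate constant (1/h).
#' @param r_q1 heat yield per gram of biomass formed (kcal/g).
#' @param r_q2 maintenance heat coefficient (kcal/(g h)).
#' @param kla0 base volumetric oxygen transfer coefficient (1/h).
#' @param cl_star dissolved oxygen saturation concentration (g/L).
#' @param evap fractional evaporative volume loss rate (1/h).
#' @param alpha1,alpha2,alpha3 CO2 evolution coefficients (growth-associated,
#'   biomass-associated, basal).
#' @param k_ph_acid,k_ph_prod pH load coefficients of growth and production.
#' @param k_ph_ctrl,k_t_ctrl proportional controller gains for pH and
#'   temperature (1/h).
#' @return a validated `kinetic_params` list.
#' @export
penicillin_params <- function(mu_x = 0.092, K_x = 0.15, mu_p = 0.005,
                              K_p = 2e-4, K_I = 0.1, K_ox = 2e-2,
                              K_op = 5e-4, Y_xs = 0.45, Y_ps = 0.90,
                              Y_xo = 0.04, Y_po = 0.20, m_x = 0.014,
                              m_o = 0.467, K_h = 0.04, r_q1 = 0.06,
                              r_q2 = 0.005, kla0 = 250, cl_star = 1.16,
                              evap = 2.5e-4, alpha1 = 0.143, alpha2 = 0.004,
                              alpha3 = 1e-4, k_ph_acid = 0.02,
                              k_ph_prod = 0.004, k_ph_ctrl = 0.5,
                              k_t_ctrl = 1.0) {
  p <- list(mu_x = mu_x, K_x = K_x, mu_p = mu_p, K_p = K_p, K_I = K_I,
            K_ox = K_ox, K_op = K_op, Y_xs = Y_xs, Y_ps = Y_ps,
            Y_xo = Y_xo, Y_po = Y_po, m_x = m_x, m_o = m_o, K_h = K_h,
            r_q1 = r_q1, r_q2 = r_q2, kla0 = kla0, cl_star = cl_star,
            evap = evap, alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
            k_ph_acid = k_ph_acid, k_ph_prod = k_ph_prod,
            k_ph_ctrl = k_ph_ctrl, k_t_ctrl = k_t_ctrl)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_bs("all kinetic parameters must be finite and strictly positive",
            "bs_bad_params")
  }
  for (y in c("Y_xs", "Y_ps", "Y_xo", "Y_po")) {
    if (p[[y]] > 10) {
      stop_bs(sprintf("yield %s = %g exceeds the sanity bound of 10 g/g",
                      y, p[[y]]), "bs_bad_params")
    }
  }
  structure(p, class = "kinetic_params")
}

#' Configuration of a single simulated fermentation batch
#'
#' @param substrate0 initial substrate concentration (g/L).
#' @param biomass0 initial biomass concentration (g/L).
#' @param product0 initial penicillin concentration (g/L).
#' @param volume0 initial culture volume (L).
#' @param do0 initial dissolved oxygen (g/L).
#' @param ph0 initial pH.
#' @param temp0 initial temperature (K); also the controller setpoint.
#' @param ph_set pH controller setpoint.
#' @param duration_h batch duration (h).
#' @param dt_h integration step of the fixed-step RK4 scheme (h); must divide
#'   `sample_period_h`.
#' @param sample_period_h sampling period of the recorded dataset (h);
#'   default 1 h.
#' @param feed_profile optional `data.frame(time, rate)` giving the substrate
#'   feed rate (L/h) as a piecewise-linear function of time. If `NULL`, a
#'   default profile is built: no feed until `feed_on_h`, then a 2 h linear
#'   ramp up to `feed_rate`.
#' @param feed_on_h feed start time (h) of the default profile.
#' @param feed_rate constant feed rate (L/h) of the default profile.
#' @param feed_substrate substrate concentration of the feed (g/L).
#' @param aeration aeration (air flow) setpoint (L/h).
#' @param agitation agitator power setpoint (W).
#' @param noise optional measurement-noise specification applied to the
#'   sampled dataset; see [add_measurement_noise()].
#' @param seed integer seed (used only if `noise` is not `NULL`).
#' @return a validated `batch_sim_config` list.
#' @export
batch_config <- function(substrate0 = 15, biomass0 = 0.1, product0 = 0,
                         volume0 = 100, do0 = 1.16, ph0 = 5.0, temp0 = 298,
                         ph_set = ph0, duration_h = 400, dt_h = 0.1,
                         sample_period_h = 1, feed_profile = NULL,
                         feed_on_h = 44, feed_rate = 0.042,
                         feed_substrate = 600, aeration = 8.6,
                         agitation = 30, noise = NULL, seed = 1) {
  if (duration_h <= 0) stop_bs("duration must be > 0", "bs_bad_config")
  if (volume0 <= 0) stop_bs("initial volume must be > 0", "bs_bad_config")
  if (dt_h <= 0 || dt_h > sample_period_h) {
    stop_bs("integration step must be positive and <= sampling period",
            "bs_bad_config")
  }
  if (abs(sample_period_h / dt_h - round(sample_period_h / dt_h)) > 1e-8) {
    stop_bs("integration step must divide the sampling period",
            "bs_bad_config")
  }
  if (min(substrate0, biomass0, product0, do0) < 0) {
    stop_bs("initial concentrations must be >= 0", "bs_bad_config")
  }
  if (is.null(feed_profile)) {
    feed_profile <- data.frame(
      time = c(0, feed_on_h, feed_on_h + 2, duration_h),
      rate = c(0, 0, feed_rate, feed_rate)
    )
  }
  if (any(feed_profile$rate < 0)) {
    stop_bs("negative feed rate in feed profile", "bs_bad_config")
  }
  structure(list(
    substrate0 = substrate0, biomass0 = biomass0, product0 = product0,
    volume0 = volume0, do0 = do0, ph0 = ph0, temp0 = temp0, ph_set = ph_set,
    duration_h = duration_h, dt_h = dt_h, sample_period_h = sample_period_h,
    feed_profile = feed_profile, feed_substrate = feed_substrate,
    aeration = aeration, agitation = agitation, noise = noise, seed = seed
  ), class = "batch_sim_config")
}

# ---- process_dataset container ---------------------------------------------

#' Construct a process dataset
#'
#' The tabular container used throughout the package: an N x M matrix of
#' measured process variables, a length-N target vector (product
#' concentration), per-sample batch ids and the sampling period.
#'
#' @param X numeric matrix (N x M) with column names.
#' @param y numeric target vector of length N.
#' @param batch_id character/factor vector of length N (recycled if scalar).
#' @param sample_period_h sampling period in hours.
#' @return an object of class `process_dataset`.
#' @export
process_dataset <- function(X, y, batch_id = "batch_01", sample_period_h = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop_bs("row count of X must equal length of y", "bs_bad_data")
  }
  if (nrow(X) < 1) stop_bs("dataset must have at least one sample",
                           "bs_bad_data")
  if (anyNA(X) || anyNA(y)) stop_bs("missing values are not allowed",
                                    "bs_bad_data")
  batch_id <- rep_len(as.character(batch_id), nrow(X))
  structure(list(X = X, y = y, batch_id = batch_id,
                 variables = colnames(X),
                 sample_period_h = sample_period_h),
            class = "process_dataset")
}

#' @export
print.process_dataset <- function(x, ...) {
  cat(sprintf("<process_dataset> %d samples x %d variables, %d batch(es), %g h sampling\n",
              nrow(x$X), ncol(x$X), length(unique(x$batch_id)),
              x$sample_period_h))
  cat("variables:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.process_dataset <- function(x) dim(x$X)

#' Coerce a process dataset to a data frame
#'
#' Columns are the process variables followed by `target` and `batch_id`.
#'
#' @param x a `process_dataset`.
#' @param ... ignored.
#' @export
as.data.frame.process_dataset <- function(x, ...) {
  df <- as.data.frame(x$X)
  df$target <- x$y
  df$batch_id <- x$batch_id
  df
}

#' Row-subset a process dataset
#'
#' @param x a `process_dataset`.
#' @param i row indices.
#' @param ... ignored.
#' @export
`[.process_dataset` <- function(x, i, ...) {
  process_dataset(x$X[i, , drop = FALSE], x$y[i], x$batch_id[i],
                  x$sample_period_h)
}

#' Concatenate process datasets row-wise
#'
#' @param ... `process_dataset` objects with identical variable sets.
#' @return a single `process_dataset`.
#' @export
combine_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && is.list(ds[[1]]) &&
      !inherits(ds[[1]], "process_dataset")) {
    ds <- ds[[1]]
  }
  v <- ds[[1]]$variables
  for (d in ds) {
    if (!identical(d$variables, v)) {
      stop_bs("variable sets differ between datasets", "bs_bad_data")
    }
  }
  process_dataset(do.call(rbind, lapply(ds, function(d) d$X)),
                  unlist(lapply(ds, function(d) d$y)),
                  unlist(lapply(ds, function(d) d$batch_id)),
                  ds[[1]]$sample_period_h)
}

# ---- mechanistic model ------------------------------------------------------

# Builds the rate evaluator for one batch. Dissolved oxygen has a time
# constant of minutes (1/kla), far below the hourly sampling grid, so it is
# treated as quasi-steady: at every evaluation CL solves
# kla(CL) * (cl_star - CL) = OUR(CL) by damped fixed-point iteration. This
# keeps the ODE system non-stiff for the fixed-step RK4 integrator.
#
# State vector (plain doubles, fixed order):
#   1 X biomass (g/L), 2 S substrate (g/L), 3 P product (g/L),
#   4 V volume (L), 5 TK temperature (K), 6 pH, 7 Q cumulative heat (kcal),
#   8 Vin cumulative fed volume (L), 9 Vloss cumulative lost volume (L).
#
# rates(t, s, want_outputs): returns the 9 derivatives, followed (when
# want_outputs) by the algebraic measured outputs
# (air, power, feed, acid, base, cool, hot, co2, CL).
make_ferm_rates <- function(cfg, par, feed_fun) {
  mu_x <- par$mu_x; K_x <- par$K_x; mu_p <- par$mu_p; K_p <- par$K_p
  K_I <- par$K_I; K_ox <- par$K_ox; K_op <- par$K_op
  Y_xs <- par$Y_xs; Y_ps <- par$Y_ps; Y_xo <- par$Y_xo; Y_po <- par$Y_po
  m_x <- par$m_x; m_o <- par$m_o; K_h <- par$K_h
  r_q1 <- par$r_q1; r_q2 <- par$r_q2; kla0 <- par$kla0
  cl_star <- par$cl_star; evap <- par$evap
  a1 <- par$alpha1; a2 <- par$alpha2; a3 <- par$alpha3
  kpa <- par$k_ph_acid; kpp <- par$k_ph_prod
  kpc <- par$k_ph_ctrl; ktc <- par$k_t_ctrl
  aer <- cfg$aeration; agi <- cfg$agitation
  sf <- cfg$feed_substrate; t_set <- cfg$temp0; ph_set <- cfg$ph_set

  cl_prev <- cfg$do0   # warm start for the quasi-steady DO solve

  function(t, s, want_outputs = FALSE) {
    X <- if (s[1] > 0) s[1] else 0
    S <- if (s[2] > 0) s[2] else 0
    P <- s[3]; V <- s[4]; TK <- s[5]; pH <- s[6]

    feed <- feed_fun(t)
    gs <- if (S > 0) S / (K_x * X + S) else 0
    ps <- if (S > 0) S / (K_p + S + S * S / K_I) else 0

    # quasi-steady dissolved oxygen
    CL <- cl_prev
    for (it in 1:40) {
      go <- if (CL > 0) CL / (K_ox * X + CL) else 0
      po <- if (CL > 0) CL / (K_op * X + CL) else 0
      mu <- mu_x * gs * go
      mupp <- mu_p * ps * po
      fg <- aer * (1 + 0.4 * (cl_star - CL) / cl_star)
      pw <- agi * (1 + 0.03 * X)
      kla <- kla0 * sqrt(fg / aer) * (pw / agi)^0.4
      our <- mu * X / Y_xo + mupp * X / Y_po + m_o * X * CL / (0.1 + CL)
      cl_new <- cl_star - our / kla
      if (cl_new < 0) cl_new <- 0
      if (abs(cl_new - CL) < 1e-12) { CL <- cl_new; break }
      CL <- 0.5 * (CL + cl_new)
    }
    cl_prev <<- CL
    go <- if (CL > 0) CL / (K_ox * X + CL) else 0
    po <- if (CL > 0) CL / (K_op * X + CL) else 0
    mu <- mu_x * gs * go
    mupp <- mu_p * ps * po
    fg <- aer * (1 + 0.4 * (cl_star - CL) / cl_star)
    pw <- agi * (1 + 0.03 * X)

    qdot <- (r_q1 * mu + r_q2) * X * V                  # kcal/h
    acid_load <- kpp * mupp * X                         # alkalinizing duty
    base_load <- kpa * mu * X                           # acidifying duty
    base <- 0.01 * V * base_load
    acid <- 0.01 * V * acid_load + 0.002
    floss <- evap * V
    dV <- feed + acid + base - floss
    dil <- dV / V

    d <- c(
      mu * X - X * dil,
      -mu * X / Y_xs - mupp * X / Y_ps - m_x * X + feed * sf / V - S * dil,
      mupp * X - K_h * P - P * dil,
      dV,
      qdot / V - ktc * (TK - t_set),
      -base_load + acid_load + kpc * (ph_set - pH),
      qdot,
      feed + acid + base,
      floss
    )
    if (!want_outputs) return(d)
    cool <- 2 * ktc * V * (if (TK > t_set) TK - t_set else 0) + 0.5 * qdot
    hot <- 1.5 / (1 + 2 * qdot) +
      2 * ktc * V * (if (t_set > TK) t_set - TK else 0)
    cer <- (a1 * mu * X + a2 * X + a3) * V
    co2 <- 0.04 + cer / (28 * fg)
    c(d, fg, pw, feed, acid, base, cool, hot, co2, CL)
  }
}

#' Simulate one fed-batch penicillin fermentation batch
#'
#' Integrates the mechanistic fermentation model with a fixed-step classical
#' 4th-order Runge-Kutta scheme at `dt_h` and records the 15 process
#' variables and the penicillin concentration at every sampling instant
#' (`sample_period_h`, 2 h, ..., up to the batch duration). The run is fully
#' deterministic; measurement noise, if requested in the config, is added
#' afterwards from the config seed.
#'
#' @param config a [batch_config()].
#' @param params a [penicillin_params()].
#' @param batch_id batch label stored in the dataset.
#' @return a [process_dataset()] with one row per sampling instant.
#' @export
simulate_batch <- function(config = batch_config(),
                           params = penicillin_params(),
                           batch_id = "batch_01") {
  stopifnot(inherits(config, "batch_sim_config"),
            inherits(params, "kinetic_params"))
  feed_fun <- stats::approxfun(config$feed_profile$time,
                               config$feed_profile$rate, rule = 2)
  rates <- make_ferm_rates(config, params, feed_fun)

  dt <- config$dt_h
  steps_per_sample <- round(config$sample_period_h / dt)
  n_samples <- floor(config$duration_h / config$sample_period_h)
  state_names <- c("biomass", "substrate", "product", "volume",
                   "temperature", "pH", "heat", "vol_in", "vol_out")

  state <- c(config$biomass0, config$substrate0, config$product0,
             config$volume0, config$temp0, config$ph0, 0, 0, 0)

  vars <- penicillin_variables()
  Xout <- matrix(NA_real_, n_samples, length(vars),
                 dimnames = list(NULL, vars))
  yout <- numeric(n_samples)

  h2 <- dt / 2
  t <- 0
  for (s in seq_len(n_samples)) {
    for (k in seq_len(steps_per_sample)) {
      k1 <- rates(t, state)
      k2 <- rates(t + h2, state + h2 * k1)
      k3 <- rates(t + h2, state + h2 * k2)
      k4 <- rates(t + dt, state + dt * k3)
      state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + dt
      # floor tiny integrator undershoots of non-negative states
      if (state[1] < 0) state[1] <- 0
      if (state[2] < 0) state[2] <- 0
      if (state[3] < 0) state[3] <- 0
      if (any(!is.finite(state))) {
        bad <- state_names[!is.finite(state)][1]
        stop_bs(sprintf("non-finite state '%s' at t = %g h", bad, t),
                "bs_integration_failure")
      }
    }
    out <- rates(t, state, want_outputs = TRUE)
    # out[10..18] = air, power, feed, acid, base, cool, hot, co2, CL
    Xout[s, ] <- c(out[10], out[11], out[12], out[13], out[14], out[15],
                   out[16], state[2], out[18], state[1], state[4], out[17],
                   state[6], state[5], state[7])
    yout[s] <- state[3]
  }
  ds <- process_dataset(Xout, yout, batch_id, config$sample_period_h)
  attr(ds, "volume_balance") <- c(dV = state[4] - config$volume0,
                                  net_fed = state[8] - state[9])
  if (!is.null(config$noise)) {
    ds <- add_measurement_noise(ds, config$noise, seed = config$seed)
  }
  ds
}

#' Simulate a multi-batch fermentation campaign
#'
#' Runs `n_batches` batches whose initial substrate, biomass and volume are
#' drawn uniformly within +/- the given relative ranges around the base
#' configuration, emulating batch-to-batch variation of a production
#' campaign.
#'
#' @param n_batches number of batches (>= 1).
#' @param base base [batch_config()].
#' @param variation named numeric vector of relative half-ranges in `[0, 1)`
#'   for `substrate`, `biomass` and `volume`.
#' @param seed integer seed controlling the initial-condition draws (and,
#'   via derived per-batch seeds, any measurement noise).
#' @param params kinetic parameters shared by all batches.
#' @return a [process_dataset()] with one `batch_id` per batch.
#' @export
simulate_campaign <- function(n_batches, base = batch_config(),
                              variation = c(substrate = 0.10,
                                            biomass = 0.10,
                                            volume = 0.05),
                              seed = 1, params = penicillin_params()) {
  if (n_batches < 1) stop_bs("n_batches must be >= 1", "bs_bad_config")
  v <- c(substrate = 0, biomass = 0, volume = 0)
  v[names(variation)] <- variation
  if (any(v < 0) || any(v >= 1)) {
    stop_bs("variation ranges must lie in [0, 1)", "bs_bad_config")
  }
  if (all(v == 0) && n_batches > 1) {
    warning("zero variation with multiple batches: all batches identical",
            call. = FALSE)
  }
  if (n_batches == 1) v[] <- 0   # a 1-batch campaign is the base batch
  mult <- with_seed(seed, matrix(stats::runif(3 * n_batches), n_batches, 3))
  batches <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    cfg <- base
    cfg$substrate0 <- base$substrate0 * (1 + v[["substrate"]] * (2 * mult[b, 1] - 1))
    cfg$biomass0   <- base$biomass0 * (1 + v[["biomass"]] * (2 * mult[b, 2] - 1))
    cfg$volume0    <- base$volume0 * (1 + v[["volume"]] * (2 * mult[b, 3] - 1))
    cfg$seed <- derive_seed(seed, b)
    batches[[b]] <- simulate_batch(cfg, params,
                                   batch_id = sprintf("batch_%02d", b))
  }
  out <- combine_datasets(batches)
  attr(out, "initials") <- data.frame(
    batch_id = sprintf("batch_%02d", seq_len(n_batches)),
    substrate0 = base$substrate0 * (1 + v[["substrate"]] * (2 * mult[, 1] - 1)),
    biomass0 = base$biomass0 * (1 + v[["biomass"]] * (2 * mult[, 2] - 1)),
    volume0 = base$volume0 * (1 + v[["volume"]] * (2 * mult[, 3] - 1)))
  out
}

#' Add Gaussian measurement noise to a process dataset
#'
#' Adds independent Gaussian noise to the input variables; the target is
#' left clean by default. For variables constrained to be non-negative the
#' noisy values are clipped at zero. The input object is not modified.
#'
#' @param data a [process_dataset()].
#' @param noise either `list(snr_db = <dB>)` — per-column SD set to the
#'   column RMS divided by `10^(snr_db/20)` — or a named numeric vector of
#'   per-variable standard deviations (name `".all"` applies one SD to every
#'   variable).
#' @param seed integer seed.
#' @param noise_target also perturb the target (default `FALSE`).
#' @return a new `process_dataset` with noisy inputs.
#' @export
add_measurement_noise <- function(data, noise, seed = 1,
                                  noise_target = FALSE) {
  stopifnot(inherits(data, "process_dataset"))
  X <- data$X
  n <- nrow(X)
  if (is.list(noise) && !is.null(noise$snr_db)) {
    rms <- sqrt(colMeans(X^2))
    sds <- rms / 10^(noise$snr_db / 20)
  } else {
    noise <- unlist(noise)
    if (any(noise < 0)) stop_bs("noise SDs must be >= 0", "bs_bad_config")
    if (identical(names(noise), ".all") || is.null(names(noise))) {
      sds <- rep(noise[[1]], ncol(X))
      names(sds) <- colnames(X)
    } else {
      unknown <- setdiff(names(noise), colnames(X))
      if (length(unknown)) {
        stop_bs(paste("unknown variable(s) in noise spec:",
                      paste(unknown, collapse = ", ")), "bs_bad_config")
      }
      sds <- stats::setNames(rep(0, ncol(X)), colnames(X))
      sds[names(noise)] <- noise
    }
  }
  E <- with_seed(seed, sweep(matrix(stats::rnorm(n * ncol(X)), n), 2,
                             sds, "*"))
  Xn <- X + E
  clip <- intersect(colnames(X), nonneg_variables())
  if (length(clip) == 0 && !identical(colnames(X), penicillin_variables())) {
    clip <- colnames(X)   # generic tables: treat all inputs as non-negative
  }
  Xn[, clip] <- pmax(Xn[, clip, drop = FALSE], 0)
  y <- data$y
  if (noise_target) {
    sdy <- if (is.list(noise) && !is.null(noise$snr_db)) {
      sqrt(mean(y^2)) / 10^(noise$snr_db / 20)
    } else mean(sds)
    y <- pmax(y + with_seed(derive_seed(seed, 999),
                            stats::rnorm(n, sd = sdy)), 0)
  }
  process_dataset(Xn, y, data$batch_id, data$sample_period_h)
}

# ---- presets and I/O --------------------------------------------------------

#' Simulate one of the packaged experiment presets
#'
#' Dataset-size presets mirroring the benchmark table sizes (800, 1600,
#' 5200 and 10000 samples, built by concatenating 400 h batches sampled
#' hourly) and the 20-batch campaign used by the moving-window experiments.
#'
#' @param name one of `"table3_1"` (800 samples), `"table3_2"` (1600),
#'   `"table3_3"` (5200), `"table3_4"` (10000), `"campaign20"` (20 training
#'   batches plus 1 clean test batch, returned as a list with elements
#'   `train` and `test`).
#' @param seed integer seed.
#' @param noise_snr_db optional SNR (dB) of measurement noise added to the
#'   generated inputs; `NULL` (default) means noise-free.
#' @return a [process_dataset()], or a list of two for `"campaign20"`.
#' @export
fermsim_preset <- function(name, seed = 1, noise_snr_db = NULL) {
  sizes <- c(table3_1 = 2, table3_2 = 4, table3_3 = 13, table3_4 = 25)
  base <- batch_config()
  if (name %in% names(sizes)) {
    ds <- simulate_campaign(sizes[[name]], base, seed = seed)
    if (!is.null(noise_snr_db)) {
      ds <- add_measurement_noise(ds, list(snr_db = noise_snr_db),
                                  seed = derive_seed(seed, 101))
    }
    return(ds)
  }
  if (identical(name, "campaign20")) {
    train <- simulate_campaign(20, base, seed = seed)
    if (!is.null(noise_snr_db)) {
      train <- add_measurement_noise(train, list(snr_db = noise_snr_db),
                                     seed = derive_seed(seed, 101))
    }
    test <- simulate_campaign(1, base, seed = derive_seed(seed, 202))
    test$batch_id <- rep("batch_test", length(test$y))
    return(list(train = train, test = test))
  }
  stop_bs(sprintf("unknown preset '%s'; available: %s", name,
                  paste(c(names(sizes), "campaign20"), collapse = ", ")),
          "bs_bad_config")
}

#' Write a process dataset to CSV
#'
#' Comma-separated, header row of variable names plus `target` and
#' `batch_id`, numeric values at 6 significant digits, LF line endings.
#'
#' @param data a [process_dataset()].
#' @param path output file path.
#' @export
write_process_csv <- function(data, path) {
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a process dataset from CSV
#'
#' @param path CSV file with a header row; one column holds the target.
#' @param target_col name of the target column (default `"target"`).
#' @param sample_period_h sampling period recorded in the returned object.
#' @return a [process_dataset()].
#' @export
read_process_csv <- function(path, target_col = "target",
                             sample_period_h = 1) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!target_col %in% names(df)) {
    stop_bs(sprintf("target column '%s' not found in %s", target_col, path),
            "bs_bad_data")
  }
  batch <- if ("batch_id" %in% names(df)) df$batch_id else "batch_01"
  keep <- setdiff(names(df), c(target_col, "batch_id"))
  process_dataset(as.matrix(df[keep]), df[[target_col]], batch,
                  sample_period_h)
}
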