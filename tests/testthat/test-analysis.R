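test_that("ISI extraction and rate conversion are exact on known trains", {
  isis <- extract_isis(c(10, 20, 35))
  expect_equal(isis$isi_ms, c(10, 15))
  expect_equal(isis$index, 1:2)
  expect_warning(e <- extract_isis(42), "fewer than 2")
  expect_equal(nrow(e), 0)

  r <- instantaneous_rate(c(0, 8.646, 2 * 8.646))
  expect_equal(r$rate_hz, rep(1000 / 8.646, 2), tolerance = 1e-12)
  expect_equal(r$time_ms[1], 8.646 / 2)
  expect_equal(first_interval_rate(c(5, 15, 100)), 100)
  expect_true(is.na(first_interval_rate(c(5), after = 0)))
})

test_that("mean rate counts spikes in the window and finds the Type I threshold", {
  expect_equal(mean_rate(numeric(0), 0, 1000), 0)
  expect_equal(mean_rate(c(100, 200, 300), 0, 1000), 3)
  expect_error(mean_rate(c(1), 5, 5), "empty")

  p <- p_std(1)
  below <- flif_simulate(p, rep(0.5, 20000), dt = 0.1)$spikes
  above <- flif_simulate(p, rep(0.7, 20000), dt = 0.1)$spikes
  expect_equal(mean_rate(below, 0, 2000), 0)
  expect_gt(mean_rate(above, 0, 2000), 0)
})

test_that("conditioning history shifts the first-interval rate but not the steady rate", {
  p <- flif_params(alpha = 0.2, preset = "adapted")
  dt <- 0.5
  run <- function(pre) {
    cur <- render_stimulus(stim_pre_post(pre, 2000, 4), round(8000 / dt), dt)
    flif_simulate(p, cur, dt = dt)$spikes
  }
  lo <- run(-2)   # hyper-polarizing conditioning
  hi <- run(2)    # depolarizing conditioning
  expect_gt(first_interval_rate(hi, after = 2000),
            first_interval_rate(lo, after = 2000))
  # steady-state rate over the last 3 s is conditioning-independent
  expect_equal(mean_rate(hi, 5000, 8000), mean_rate(lo, 5000, 8000),
               tolerance = 0.06)
})

test_that("impedance of the classical membrane matches the RC closed form", {
  p <- p_std(1)
  dt <- 0.1
  n <- 100000
  cur <- zap_current(n, dt, 0.1, steepness = 2)  # cover the full band
  sim <- flif_simulate(p, cur, dt = dt)
  expect_length(sim$spikes, 0)
  zp <- impedance_profile(sim$voltage[-1], sim$current[-1], dt)
  rc <- 1 / (p$g_L * sqrt(1 + (2 * pi * zp$freq_hz / 1000 * p$tau_m)^2))
  expect_lt(max(abs(zp$magnitude_Mohm - rc) / rc), 0.02)
  # DC limit 1/g_L = 40 MOhm; phase ~ 0 at DC, approaching -90 at high f
  expect_equal(zp$magnitude_Mohm[1], 40, tolerance = 0.02 * 40)
  expect_gt(zp$phase_deg[1], -10)
  expect_lt(zp$phase_deg[which.min(abs(zp$freq_hz - 95))], -80)
  expect_error(impedance_profile(sim$voltage[-1], sim$current[-1], dt,
                                 spikes = c(1)), "sub-threshold")
})

test_that("low exponents flatten the impedance and shrink the phase lag", {
  dt <- 0.2
  n <- 50000
  cur <- zap_current(n, dt, 0.1, steepness = 2)
  band_ratio <- function(a) {
    sim <- flif_simulate(p_std(a), cur, dt = dt)
    zp <- impedance_profile(sim$voltage[-1], sim$current[-1], dt)
    lo <- zp$magnitude_Mohm[which.min(abs(zp$freq_hz - 2))]
    hi <- zp$magnitude_Mohm[which.min(abs(zp$freq_hz - 90))]
    ph <- zp$phase_deg[which.min(abs(zp$freq_hz - 90))]
    c(ratio = lo / hi, phase_hi = ph)
  }
  b1 <- band_ratio(1)
  b2 <- band_ratio(0.2)
  expect_gt(b1["ratio"], 5)            # steep classical low-pass
  expect_lt(b2["ratio"], 3)            # flattened fractional profile
  expect_gt(b2["phase_hi"], b1["phase_hi"])  # smaller lag at low alpha
})

test_that("sinusoidal rate fits recover amplitude and phase exactly on synthetic data", {
  P <- 2000
  tt <- seq(0, 8000, by = 10)
  rate <- data.frame(time_ms = tt,
                     rate_hz = 30 + 5 * sin(2 * pi * tt / P + pi / 6))
  gp <- gain_phase_at_period(rate, P, current_amplitude = 0.5)
  expect_equal(gp$gain, 10, tolerance = 1e-9)
  expect_equal(gp$phase_deg, 30, tolerance = 1e-9)
  expect_lt(gp$residual, 1e-9)
  expect_error(gain_phase_at_period(rate[tt < 3000, ], P, 0.5),
               "cycles")
})

test_that("exponential adaptation fits recover a known time constant", {
  tt <- seq(0, 4000, by = 25)
  r <- data.frame(time_ms = tt, rate_hz = 20 + 15 * exp(-tt / 500))
  fit <- fit_adaptation_tau(r, c(0, 4000), "downward")
  expect_equal(fit$tau_ms, 500, tolerance = 1e-6)
  expect_equal(fit$r_inf, 20, tolerance = 1e-6)
  expect_error(fit_adaptation_tau(r[1:3, ], c(0, 100)), "too few")
})

test_that("log-binned ISI histograms separate power laws from exponentials", {
  expect_error(isi_powerlaw_fit(rep(10, 30)), "occupied")
  expect_error(isi_powerlaw_fit(1:10), "at least 20")
  # Pareto tail exponent 2: log-bin counts fall with slope ~ -2
  x <- with_seed_test(5, 10 / runif(5000)^(1 / 2))
  fit <- isi_powerlaw_fit(x[x < 1e4])
  expect_equal(fit$slope, -2, tolerance = 0.25)
  expect_gt(fit$r_squared, 0.9)
  # exponential ISIs are fit better by the log-linear model
  y <- with_seed_test(6, stats::rexp(5000, 1 / 50)) + 5
  efit <- isi_powerlaw_fit(y)
  expect_gt(efit$r_squared_exp, efit$r_squared)
})

test_that("reliability is 1 for identical trains, ~0 for disjoint ones, and symmetric", {
  tr <- list(c(100, 300, 700), c(100, 300, 700), c(100, 300, 700))
  expect_equal(reliability(tr, smoothing_sigma = 3, dt = 1)$R, 1,
               tolerance = 1e-9)
  far <- list(100, 900)
  expect_lt(reliability(far, smoothing_sigma = 3, dt = 1,
                        epoch = c(0, 1000))$R, 1e-6)
  mix <- list(c(100, 350), c(120, 340, 800), c(90, 300))
  r1 <- reliability(mix, smoothing_sigma = 10, dt = 1, epoch = c(0, 1000))$R
  r2 <- reliability(rev(mix), smoothing_sigma = 10, dt = 1,
                    epoch = c(0, 1000))$R
  expect_equal(r1, r2, tolerance = 1e-12)
  # invariant under a common global shift
  sh <- reliability(lapply(mix, `+`, 200), smoothing_sigma = 10, dt = 1,
                    epoch = c(200, 1200))$R
  expect_equal(sh, r1, tolerance = 1e-9)
  expect_warning(
    rz <- reliability(list(c(100, 200), numeric(0), c(110, 210)),
                      smoothing_sigma = 5, dt = 1, epoch = c(0, 500)),
    "excluded")
  expect_equal(rz$n_trials, 2)
  expect_error(suppressWarnings(
    reliability(list(numeric(0), numeric(0)), epoch = c(0, 100))),
    "fewer than 2")
})

test_that("pause and cycle-recovery metrics handle edge cases", {
  pp <- pause_after_pulse(c(10, 20, 150), pulse_end = 100)
  expect_equal(pp$pause_ms, 50)
  expect_false(pp$censored)
  cens <- pause_after_pulse(c(10, 20), pulse_end = 100, t_max = 500)
  expect_true(cens$censored)
  expect_equal(cens$pause_ms, 400)
  expect_error(pause_after_pulse(c(200), pulse_end = 100), "before")

  same <- replicate(5, c(30, 25, 22, 20), simplify = FALSE)
  expect_equal(cycle_recovery_metric(same), 1)
  expect_error(cycle_recovery_metric(c(same[1:4], list(c(1, 2)))),
               "fewer than 3")
})

test_that("classical pause after a pulse is bounded by one recharge cycle", {
  p <- p_std(1)
  pauses <- vapply(c(1, 4), function(A) {
    protocol_pause(p, baseline = 1, pulse_amplitude = A, pre_ms = 500,
                   pulse_ms = 500, post_ms = 500, dt = 0.1)$pause_ms
  }, numeric(1))
  # memoryless: firing resumes within one reset-to-threshold cycle at the
  # baseline current, however strong the preceding pulse was
  expect_true(all(pauses <= lif_isi(1, p) + 0.2))
  expect_true(all(pauses > 0))
})
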