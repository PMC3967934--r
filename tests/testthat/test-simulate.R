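test_that("alpha = 1 reproduces the classical LIF: charging curve and ISI", {
  p <- p_std(1)
  # sub-threshold charging matches the exponential solution
  sim <- flif_simulate(p, rep(0.3, 5000), dt = 0.1)
  expect_length(sim$spikes, 0)
  err <- max(abs(sim$voltage - lif_voltage(sim$time, 0.3, p)))
  expect_lt(err, 0.02)    # first-order Euler at dt = 0.1
  # voltage approaches V_L + I/g_L = -58 mV from below
  expect_true(all(sim$voltage <= -58))
  expect_gt(sim$voltage[5001], -58.1)

  # steady ISI at 3 nA matches tau_ref + tau_m * log(1.2) within one dt
  sim2 <- flif_simulate(p, rep(3, 3000), dt = 0.1)
  isis <- diff(sim2$spikes)
  expect_true(all(abs(isis - lif_isi(3, p)) <= 0.1 + 1e-9))
})

test_that("classical-limit discretization error shrinks linearly with dt", {
  p <- p_std(1)
  errs <- vapply(c(0.4, 0.2, 0.1, 0.05), function(dt) {
    sim <- flif_simulate(p, rep(0.3, round(200 / dt)), dt = dt)
    max(abs(sim$voltage - lif_voltage(sim$time, 0.3, p)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[1] / errs[4], 4)      # at least ~first-order
})

test_that("fractional sub-threshold trace converges to the Mittag-Leffler solution", {
  for (a in c(0.5, 0.8)) {
    p <- p_std(a)
    errs <- vapply(c(1, 0.5, 0.1, 0.05), function(dt) {
      sim <- flif_simulate(p, rep(0.3, round(1000 / dt)), dt = dt)
      ref <- subthreshold_voltage(sim$time, 0.3, p)
      max(abs(sim$voltage - ref))
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
    expect_lt(errs[4], 0.05)
  }
})

test_that("early sub-threshold response is a power law with exponent alpha", {
  slope_err <- vapply(c(0.5, 0.3), function(a) {
    p <- p_std(a)
    dt <- 0.025
    sim <- flif_simulate(p, rep(0.3, round(12 / dt)), dt = dt)
    keep <- sim$time >= 0.25 & sim$time <= 5
    fit <- lm(log(sim$voltage[keep] - p$V_0) ~ log(sim$time[keep]))
    expect_gt(summary(fit)$r.squared, 0.999)
    abs(unname(coef(fit)[2]) - a)
  }, numeric(1))
  expect_true(all(slope_err < 0.05))
  expect_lt(slope_err[2], slope_err[1])  # cleaner power law at lower alpha
})

test_that("low exponents lengthen the first-spike latency and shrink ISIs over time", {
  lat <- vapply(c(0.2, 0.4, 0.6, 0.8, 1), function(a) {
    flif_simulate(p_std(a), rep(3, 20000), dt = 0.1)$spikes[1]
  }, numeric(1))
  expect_true(all(diff(lat) <= 1e-9))      # monotone non-increasing in alpha
  expect_gt(lat[1], lat[5])

  isis <- diff(flif_simulate(p_std(0.2), rep(3, 20000), dt = 0.1)$spikes)
  expect_true(all(diff(isis) < 0))         # spiking accelerates
})

test_that("spike train invariants hold across exponents", {
  for (a in c(0.2, 0.6, 1)) {
    p <- p_std(a)
    sim <- flif_simulate(p, rep(3, 20000), dt = 0.1)
    expect_true(all(sim$voltage <= p$V_th + 1e-12))
    expect_gt(length(sim$spikes), 1)
    expect_true(all(diff(sim$spikes) >= p$tau_ref - 1e-9))
    # voltage is clamped at V_reset through the refractory period
    k <- round(sim$spikes[1] / 0.1) + 1
    expect_equal(sim$voltage[k], p$V_th)
    expect_true(all(sim$voltage[(k + 1):(k + 49)] == p$V_reset))
  }
})

test_that("memory trace turns negative after a reset and the run is deterministic", {
  p <- p_std(0.2)
  sim <- flif_simulate(p, rep(3, 10000), dt = 0.1)
  k <- round(sim$spikes[1] / 0.1) + 1
  # the reset increment enters the memory sum right after the spike sample
  expect_lt(min(sim$memory_trace[(k + 2):(k + 20)]), 0)
  pre <- sim$memory_trace[(k - 20):(k - 1)]
  expect_true(all(pre > 0))                # depolarizing approach to spike
  sim2 <- flif_simulate(p, rep(3, 10000), dt = 0.1)
  expect_identical(sim$voltage, sim2$voltage)
  expect_identical(sim$spikes, sim2$spikes)
})

test_that("memory reset on spike produces regular spiking after the first spike", {
  p <- p_std(0.3)
  sim <- flif_simulate(p, rep(3, 30000), dt = 0.1,
                       memory_mode = "reset_on_spike")
  isis <- diff(sim$spikes)
  expect_gt(length(isis), 10)
  expect_true(all(abs(isis[-1] - isis[2]) <= 0.1 + 1e-9))
  # whereas the full model's ISIs keep shrinking toward the refractory bound
  full <- diff(flif_simulate(p, rep(3, 30000), dt = 0.1)$spikes)
  expect_true(all(diff(full) <= 0.1 + 1e-9))   # within one-dt jitter
  expect_lt(tail(full, 1), 0.75 * full[1])
})

test_that("the R reference stepper reproduces the compiled simulator", {
  p <- flif_params(alpha = 0.4, g_L = 0.05)   # tau_m = 10: spikes quickly
  cur <- c(rep(3, 150), rep(0.2, 50))
  for (mode in c("full", "reset_on_spike")) {
    sim <- flif_simulate(p, cur, dt = 0.5, memory_mode = mode)
    st <- flif_state_init(p)
    for (k in seq_along(cur)) {
      st <- flif_advance(st, cur[k], dt = 0.5, memory_mode = mode)
    }
    expect_gt(length(sim$spikes), 0)
    expect_equal(st$history, sim$voltage, tolerance = 1e-12)
    expect_equal(st$spikes, sim$spikes, tolerance = 1e-12)
  }
})

test_that("bad inputs are rejected with informative errors", {
  p <- p_std(0.5)
  expect_error(flif_simulate(p, numeric(0)), "current")
  expect_error(flif_simulate(p, c(1, NA)), "current")
  expect_error(flif_simulate(p, rep(1, 10), dt = -1), "dt")
})
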