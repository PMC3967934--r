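test_that("step and conditioning protocols render piecewise-constant currents", {
  expect_equal(render_stimulus(stim_step(3), 10, 0.1), rep(3, 10))
  s <- render_stimulus(stim_step(3, onset = 1, duration = 2, baseline = 0.5),
                       50, 0.1)
  expect_equal(unique(s), c(0.5, 3))
  expect_equal(sum(s == 3), 20)

  pp <- render_stimulus(stim_pre_post(-3, 5, 3), 100, 0.1)
  expect_equal(pp[1:50], rep(-3, 50))
  expect_equal(pp[51:100], rep(3, 50))
  expect_equal(sum(diff(pp) != 0), 1)      # a single discontinuity
})

test_that("square waves alternate exact half-periods", {
  sq <- render_stimulus(stim_square(3.4, 4, 16000), 64000, 0.5)
  expect_equal(sq[1:16000], rep(3.4, 16000))
  expect_equal(sq[16001:32000], rep(4, 16000))
  expect_equal(sq[32001:48000], rep(3.4, 16000))
  r <- rle(sq)
  expect_true(all(r$lengths == 16000))
})

test_that("ZAP current sweeps frequency monotonically without phase jumps", {
  expect_equal(zap_current(100, 0.1, 0), rep(0, 100))

  # degenerate sweep: pure 10 Hz tone with FFT peak at 10 Hz
  n <- 20000; dt <- 0.1
  z <- zap_current(n, dt, 1, f_lo = 10, f_hi = 10)
  spec <- Mod(fft(z))[1:(n / 2)]
  fpk <- (which.max(spec) - 1) / (n * dt / 1000)
  expect_equal(fpk, 10, tolerance = 0.1)

  # 0->100 Hz sweep: zero-crossing spacing non-increasing (freq non-decreasing)
  zz <- zap_current(100000, 0.1, 1)
  cross <- which(diff(sign(zz)) != 0) * 0.1
  gaps <- diff(cross)
  expect_true(all(diff(gaps) <= 0.1 + 1e-9))   # allow one-sample jitter
  expect_gt(gaps[1], 40)                        # ~ < 12 Hz at the start
  expect_lt(tail(gaps, 1), 6)                   # ~ > 83 Hz at the end
})

test_that("alpha filter has unit gain, peak at tau, and smooths by tau", {
  dt <- 0.1
  imp <- c(1, rep(0, 999))
  y <- alpha_filter(imp, tau = 5, dt = dt)
  expect_equal((which.max(y) - 2) * dt, 5, tolerance = dt)
  expect_equal(sum(y), 1, tolerance = 1e-9)

  const <- alpha_filter(rep(2, 2000), tau = 5, dt = dt)
  expect_equal(tail(const, 1), 2, tolerance = 1e-6)

  ac_time <- function(tau) {
    x <- alpha_filter(with_seed_test(42, rnorm(20000)), tau, dt)
    a <- acf(x, lag.max = 1000, plot = FALSE)$acf
    which(a < exp(-1))[1] * dt
  }
  expect_gt(ac_time(20), ac_time(2))
  expect_error(alpha_filter(imp, tau = 0, dt = dt), "tau")
})

test_that("noisy currents are reproducible by seed and follow the variance schedule", {
  n <- 8000; dt <- 0.5
  expect_equal(noisy_current(100, dt, 3, 0), rep(3, 100))

  a <- noisy_current(n, dt, 0, 1, seed = 7)
  b <- noisy_current(n, dt, 0, 1, seed = 7)
  cc <- noisy_current(n, dt, 0, 1, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, cc))

  sched <- list(c(500, 1), c(500, 4), c(500, 2), c(500, 1),
                c(500, 2), c(500, 1), c(500, 4), c(500, 2))
  x <- noisy_current(n, dt, 0, 1, tau_filter = 2, seed = 3,
                     variance_schedule = sched)
  sds <- vapply(1:8, function(i) sd(x[((i - 1) * 1000 + 1):(i * 1000)]),
                numeric(1))
  sig <- c(1, 4, 2, 1, 2, 1, 4, 2)
  expect_gt(min(sds[sig == 4]), max(sds[sig == 2]))
  expect_gt(min(sds[sig == 2]), max(sds[sig == 1]))
  expect_error(noisy_current(n, dt, 0, 1,
                             variance_schedule = list(c(500, 1))), "schedule")
})

test_that("rendering is a pure function of spec, grid and seed", {
  spec <- stim_noisy(1, 0.5, seed = 11)
  expect_identical(render_stimulus(spec, 500, 0.5),
                   render_stimulus(spec, 500, 0.5))
  z <- render_stimulus(stim_zap(0.1), 5000, 0.5)
  expect_true(all(is.finite(z)))
  expect_error(render_stimulus(structure(list(variant = "wiggle"),
                                         class = "flif_stimulus"),
                               10, 0.1), "unknown stimulus")
})

test_that("embedded-signal stimuli share the frozen component across trials", {
  mk <- function(seed, seed_signal) {
    render_stimulus(stim_embedded(0.5, sigma_intrinsic = 0.1,
                                  sigma_signal = 1, tau_filter = 2,
                                  seed = seed, seed_signal = seed_signal),
                    4000, 0.5)
  }
  a <- mk(1, 100); b <- mk(2, 100); c <- mk(2, 200)
  expect_identical(mk(1, 100), a)            # fully seeded
  expect_gt(cor(a, b), 0.9)                  # same embedded signal dominates
  expect_lt(abs(cor(a, c)), 0.3)             # different embedded signal
})

test_that("run configs with unbounded step durations survive YAML round-trips", {
  cfg <- flif_protocol("fig1-step")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_identical(render_stimulus(back$stimulus, 200, back$dt),
                   render_stimulus(cfg$stimulus, 200, cfg$dt))
})
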