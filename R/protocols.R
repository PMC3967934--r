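#' Five-cycle step protocol with inter-stimulus gaps
#'
#' Five identical supra-threshold current steps separated by silent gaps,
#' the protocol used to probe how long the adaptation memory persists
#' between stimulation episodes. Returns the spikes of each cycle and their
#' inter-spike intervals, ready for [cycle_recovery_metric()].
#'
#' @param params a [flif_params()] object.
#' @param amplitude step amplitude (nA).
#' @param cycle_ms step (cycle) duration (ms).
#' @param gap_ms silent gap between cycles (ms).
#' @param n_cycles number of cycles.
#' @param dt time step (ms).
#' @return List: `isis_by_cycle` (list of ISI vectors), `spikes_by_cycle`,
#'   `sim` (the full [flif_simulate()] result).
#' @export
protocol_five_cycles <- function(params, amplitude = 4, cycle_ms = 1000,
                                 gap_ms = 1000, n_cycles = 5, dt = 0.5) {
  n_on <- as.integer(round(cycle_ms / dt))
  n_off <- as.integer(round(gap_ms / dt))
  one <- c(rep(amplitude, n_on), rep(0, n_off))
  current <- c(rep(one, n_cycles - 1), rep(amplitude, n_on))
  sim <- flif_simulate(params, current, dt = dt)
  starts <- (seq_len(n_cycles) - 1) * (cycle_ms + gap_ms)
  spikes_by_cycle <- lapply(starts, function(s0) {
    sim$spikes[sim$spikes > s0 & sim$spikes <= s0 + cycle_ms]
  })
  isis_by_cycle <- lapply(spikes_by_cycle, function(s) {
    if (length(s) < 2) numeric(0) else diff(s)
  })
  list(isis_by_cycle = isis_by_cycle, spikes_by_cycle = spikes_by_cycle,
       sim = sim)
}

#' Adaptation recovery as a function of the inter-stimulus gap
#'
#' Runs [protocol_five_cycles()] over a sweep of gap lengths and reports the
#' second-to-last-ISI recovery ratio (Cycle 5 / Cycle 1) and the first ISIs
#' of both cycles for each gap.
#'
#' @inheritParams protocol_five_cycles
#' @param gaps_ms gap lengths to test (ms).
#' @return Data frame: `gap_ms`, `ratio`, `first_isi_c1`, `first_isi_c5`.
#' @export
gap_recovery_curve <- function(params, gaps_ms, amplitude = 4,
                               cycle_ms = 1000, dt = 0.5) {
  rows <- lapply(gaps_ms, function(g) {
    pc <- protocol_five_cycles(params, amplitude = amplitude,
                               cycle_ms = cycle_ms, gap_ms = g, dt = dt)
    data.frame(
      gap_ms = g,
      ratio = cycle_recovery_metric(pc$isis_by_cycle),
      first_isi_c1 = pc$isis_by_cycle[[1]][1],
      first_isi_c5 = pc$isis_by_cycle[[5]][1])
  })
  do.call(rbind, rows)
}

#' Post-pulse pause protocol
#'
#' A constant supra-threshold baseline with a square pulse of the given
#' amplitude riding on top for `pulse_ms`; the pause of the spiking activity
#' after the pulse is turned off is measured with [pause_after_pulse()].
#'
#' @inheritParams protocol_five_cycles
#' @param baseline baseline current (nA), supra-threshold.
#' @param pulse_amplitude additional pulse current (nA).
#' @param pre_ms baseline time before the pulse (ms).
#' @param pulse_ms pulse duration (ms).
#' @param post_ms baseline time after the pulse (ms).
#' @return List: `pause_ms`, `censored`, `sim`.
#' @export
protocol_pause <- function(params, baseline = 1, pulse_amplitude = 4,
                           pre_ms = 1000, pulse_ms = 1000, post_ms = 3000,
                           dt = 0.5) {
  current <- c(rep(baseline, round(pre_ms / dt)),
               rep(baseline + pulse_amplitude, round(pulse_ms / dt)),
               rep(baseline, round(post_ms / dt)))
  sim <- flif_simulate(params, current, dt = dt)
  pulse_end <- pre_ms + pulse_ms
  pp <- pause_after_pulse(sim$spikes, pulse_end,
                          t_max = pre_ms + pulse_ms + post_ms)
  c(pp, list(sim = sim))
}

#' Gain-versus-period study under sinusoidal drive
#'
#' Simulates supra-threshold sine-wave stimulation at several periods,
#' extracts the instantaneous firing rate, fits the rate sinusoid at each
#' known period ([gain_phase_at_period()]), and fits a line to
#' log10(gain) versus log10(period). For a fractional differentiator the
#' slope of that line is minus the fractional exponent.
#'
#' Each period is simulated from rest and the whole rate trace is fitted
#' (no cycles are discarded by default): the response of the freshly
#' stimulated neuron, with its memory building up during the epoch, is what
#' exhibits the clean power-law gain.
#'
#' @inheritParams protocol_five_cycles
#' @param periods_ms sine periods (ms).
#' @param mean_nA,amplitude_nA sine mean and amplitude (nA).
#' @param n_cycles simulated cycles per period.
#' @param n_discard initial cycles discarded before the sine fit.
#' @return List: `table` (period, gain, phase), `slope`, `r_squared`.
#' @export
protocol_gain_study <- function(params, periods_ms = c(2, 4, 8, 16) * 1000,
                                mean_nA = 2.5, amplitude_nA = 0.3,
                                n_cycles = 3, n_discard = 0, dt = 0.5) {
  rows <- lapply(periods_ms, function(P) {
    n <- as.integer(round(n_cycles * P / dt))
    cur <- render_stimulus(stim_sine(amplitude_nA, P, mean = mean_nA), n, dt)
    sim <- flif_simulate(params, cur, dt = dt)
    gp <- gain_phase_at_period(instantaneous_rate(sim$spikes), P,
                               amplitude_nA, n_discard_cycles = n_discard,
                               min_cycles = n_cycles - n_discard - 1)
    data.frame(period_ms = P, gain = gp$gain, phase_deg = gp$phase_deg)
  })
  tab <- do.call(rbind, rows)
  fit <- lm(log10(gain) ~ log10(period_ms), data = tab)
  list(table = tab, slope = unname(coef(fit)[2]),
       r_squared = summary(fit)$r.squared)
}

#' Calibrate a constant current to a target mean firing rate
#'
#' Bisects the constant injected current until the mean rate over the
#' analysis window matches the target, the procedure used to match firing
#' rates across fractional exponents before comparing reliability.
#'
#' @inheritParams protocol_five_cycles
#' @param target_hz target mean rate (spikes/s).
#' @param duration_ms simulated span (ms).
#' @param window analysis window `c(start, end)` (ms); default the second
#'   half.
#' @param bounds initial current bracket (nA).
#' @param iter bisection iterations.
#' @return The calibrated current (nA).
#' @export
calibrate_current <- function(params, target_hz = 14, duration_ms = 4000,
                              window = NULL, bounds = NULL, iter = 12,
                              dt = 0.5) {
  if (is.null(window)) window <- c(duration_ms / 2, duration_ms)
  if (is.null(bounds)) {
    thr <- threshold_current(params)
    bounds <- c(thr, thr * 40)
  }
  n <- as.integer(round(duration_ms / dt))
  rate_at <- function(I) {
    sim <- flif_simulate(params, rep(I, n), dt = dt)
    mean_rate(sim$spikes, window[1], window[2])
  }
  lo <- bounds[1]; hi <- bounds[2]
  while (rate_at(hi) < target_hz) hi <- hi * 2
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) < target_hz) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Spike-time reliability study across fractional exponents
#'
#' For each exponent: calibrate the mean current to the target rate, then
#' run `n_trials` simulations that share a frozen stimulus statistics but
#' differ in the noise seed, and compute the correlation-based reliability
#' over the analysis epoch.
#'
#' @inheritParams calibrate_current
#' @param alphas fractional exponents to compare.
#' @param n_trials trials per exponent.
#' @param sigma per-sample white-noise standard deviation (nA) before
#'   alpha-filtering.
#' @param tau_filter alpha-filter time constant (ms).
#' @param smoothing_sigma Gaussian smoothing width for the reliability (ms).
#' @param seed base seed; trial seeds derive from it.
#' @param epoch_frac fraction of the span (at the end) analyzed.
#' @return Data frame: `alpha`, `current_nA`, `mean_rate_hz`, `R`.
#' @export
protocol_reliability_study <- function(alphas = c(1, 0.6, 0.2),
                                       n_trials = 20, target_hz = 14,
                                       sigma = 0.03, tau_filter = 2,
                                       smoothing_sigma = 3,
                                       duration_ms = 10000, dt = 0.5,
                                       seed = 1, epoch_frac = 0.5,
                                       preset = "table1") {
  epoch <- c(duration_ms * (1 - epoch_frac), duration_ms)
  n <- as.integer(round(duration_ms / dt))
  rows <- lapply(seq_along(alphas), function(ai) {
    a <- alphas[ai]
    p <- flif_params(alpha = a, preset = preset)
    I0 <- calibrate_current(p, target_hz = target_hz,
                            duration_ms = duration_ms, window = epoch,
                            dt = dt)
    trains <- lapply(seq_len(n_trials), function(tr) {
      cur <- noisy_current(n, dt, mean = I0, sigma = sigma,
                           tau_filter = tau_filter,
                           seed = seed + 10000L * ai + tr)
      flif_simulate(p, cur, dt = dt)$spikes
    })
    rel <- reliability(trains, smoothing_sigma = smoothing_sigma,
                       dt = max(dt, 1), epoch = epoch)
    data.frame(alpha = a, current_nA = I0,
               mean_rate_hz = mean(vapply(trains, function(s)
                 mean_rate(s, epoch[1], epoch[2]), numeric(1))),
               R = rel$R)
  })
  do.call(rbind, rows)
}

#' Square-wave adaptation time-constant study
#'
#' Alternating two-level square drive; fits the downward (after the upward
#' input step) and upward (after the downward input step) adaptation time
#' constants of the instantaneous rate within each half-period.
#'
#' @inheritParams protocol_five_cycles
#' @param period_ms square period (ms).
#' @param low,high current levels (nA).
#' @param n_periods simulated periods (the first is discarded).
#' @return List: `tau_down_ms`, `tau_up_ms`, `rate`, `sim`.
#' @export
protocol_square_adaptation <- function(params, period_ms, low = 3.4,
                                       high = 4, n_periods = 3, dt = 0.5) {
  n <- as.integer(round(n_periods * period_ms / dt))
  cur <- render_stimulus(stim_square(low, high, period_ms), n, dt)
  sim <- flif_simulate(params, cur, dt = dt)
  rate <- instantaneous_rate(sim$spikes)
  half <- period_ms / 2
  # discard the first period, then fold the remaining cycles onto one
  # period so every transient is fit on the pooled points (the adaptation
  # time constants are constant across cycles at fixed period)
  keep <- rate[rate$time_ms >= period_ms, ]
  folded <- data.frame(time_ms = keep$time_ms %% period_ms,
                       rate_hz = keep$rate_hz)
  folded <- folded[order(folded$time_ms), ]
  # margin keeps out rate points whose defining interval straddles a level
  # transition (their midpoints fall on the wrong side of the edge)
  m <- 50
  up_win <- c(m, half - m)                 # low level: rate recovers upward
  down_win <- c(half + m, period_ms - m)   # high level: rate decays downward
  fd <- fit_adaptation_tau(folded, down_win, "downward")
  fu <- fit_adaptation_tau(folded, up_win, "upward")
  list(tau_down_ms = fd$tau_ms, tau_up_ms = fu$tau_ms, rate = rate,
       sim = sim, fit_down = fd, fit_up = fu)
}
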