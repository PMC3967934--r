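#' Inter-spike intervals of a spike train
#'
#' @param spikes numeric vector of spike times (ms), strictly increasing.
#' @return A data frame with `index` (1-based ISI number) and `isi_ms`
#'   (consecutive spike-time differences). Fewer than 2 spikes give an empty
#'   data frame with a warning.
#' @export
extract_isis <- function(spikes) {
  if (length(spikes) < 2) {
    warning("fewer than 2 spikes: no inter-spike intervals", call. = FALSE)
    return(data.frame(index = integer(0), isi_ms = numeric(0)))
  }
  isi <- diff(spikes)
  data.frame(index = seq_along(isi), isi_ms = isi)
}

#' Latency from stimulus onset to the first spike
#'
#' @inheritParams extract_isis
#' @param stimulus_onset onset time (ms).
#' @return First spike time at or after the onset, minus the onset;
#'   `NA_real_` if the train contains no such spike.
#' @export
first_spike_latency <- function(spikes, stimulus_onset = 0) {
  s <- spikes[spikes >= stimulus_onset]
  if (length(s) == 0) return(NA_real_)
  s[1] - stimulus_onset
}

#' Instantaneous firing rate from inter-spike intervals
#'
#' The reciprocal of each inter-spike interval (1000/ISI, spikes/s) placed at
#' the interval midpoint. The rate of the first interval after a stimulus
#' transition (`first_interval_rate()`) is the history-sensitive quantity
#' used to compare conditioning protocols.
#'
#' @inheritParams extract_isis
#' @return Data frame with `time_ms` (interval midpoints) and `rate_hz`.
#' @export
instantaneous_rate <- function(spikes) {
  isis <- extract_isis(spikes)
  if (nrow(isis) == 0) {
    return(data.frame(time_ms = numeric(0), rate_hz = numeric(0)))
  }
  mid <- (spikes[-length(spikes)] + spikes[-1]) / 2
  data.frame(time_ms = mid, rate_hz = 1000 / isis$isi_ms)
}

#' @rdname instantaneous_rate
#' @param after only intervals starting at or after this time (ms) count.
#' @return `first_interval_rate()`: 1000 over the first ISI (spikes/s), or
#'   `NA_real_` with fewer than two qualifying spikes.
#' @export
first_interval_rate <- function(spikes, after = 0) {
  s <- spikes[spikes >= after]
  if (length(s) < 2) return(NA_real_)
  1000 / (s[2] - s[1])
}

#' Mean firing rate over a time window
#'
#' Spike count in `(window_start, window_end]` divided by the window length.
#'
#' @inheritParams extract_isis
#' @param window_start,window_end window bounds (ms).
#' @return Rate in spikes/s.
#' @export
mean_rate <- function(spikes, window_start, window_end) {
  if (window_end <= window_start) stop("empty window", call. = FALSE)
  n <- sum(spikes > window_start & spikes <= window_end)
  1000 * n / (window_end - window_start)
}

#' Membrane impedance profile from a sub-threshold epoch
#'
#' Frequency-domain ratio of the voltage response to the injected current,
#' `Z(f) = F(V) / F(I)` on mean-subtracted signals with a single
#' (non-windowed) FFT of the whole epoch. With voltage in mV and current in
#' nA the magnitude is in megaohms. The phase is negative when the voltage
#' lags the current (classical RC membrane: 0 degrees at DC, approaching
#' -90 degrees at high frequency). Impedance is a sub-threshold quantity:
#' supplying a non-empty `spikes` vector is an error.
#'
#' @param voltage voltage samples (mV).
#' @param current current samples (nA), same length.
#' @param dt time step (ms).
#' @param f_range band to report (Hz), default 1-100.
#' @param smooth_bw boxcar smoothing bandwidth for the magnitude (Hz);
#'   0 disables. Default 1 Hz.
#' @param spikes spike times detected in the epoch; must be empty.
#' @return Data frame of class `"impedance_profile"` with `freq_hz`,
#'   `magnitude_Mohm`, `phase_deg`, `resistance_Mohm`, `reactance_Mohm`.
#' @export
impedance_profile <- function(voltage, current, dt, f_range = c(1, 100),
                              smooth_bw = 1, spikes = numeric(0)) {
  if (length(spikes) > 0) {
    stop("spiking detected in the epoch: impedance is a sub-threshold ",
         "quantity; use a smaller stimulus amplitude", call. = FALSE)
  }
  if (length(voltage) != length(current)) {
    stop("voltage and current must have the same length", call. = FALSE)
  }
  n <- length(voltage)
  Z <- fft(voltage - mean(voltage)) / fft(current - mean(current))
  freq <- (seq_len(n) - 1) / (n * dt / 1000)       # Hz
  keep <- freq >= f_range[1] & freq <= f_range[2]
  freq <- freq[keep]
  Z <- Z[keep]
  mag <- Mod(Z)
  if (smooth_bw > 0) {
    df <- 1000 / (n * dt)
    w <- max(1L, as.integer(round(smooth_bw / df)))
    if (w > 1) {
      k <- rep(1 / w, w)
      mag <- as.numeric(stats::filter(mag, k, sides = 2))
      # edges: shrink the boxcar rather than dropping bins
      na <- which(is.na(mag))
      for (i in na) {
        lo <- max(1, i - w %/% 2); hi <- min(length(Z), i + w %/% 2)
        mag[i] <- mean(Mod(Z[lo:hi]))
      }
    }
  }
  ph <- Arg(Z) * 180 / pi
  ph <- ((ph + 180) %% 360) - 180
  ph[ph == -180] <- 180
  structure(data.frame(freq_hz = freq, magnitude_Mohm = mag,
                       phase_deg = ph,
                       resistance_Mohm = Re(Z), reactance_Mohm = Im(Z)),
            class = c("impedance_profile", "data.frame"))
}

#' Firing-rate gain and phase at a known stimulus period
#'
#' Least-squares fit of `rate(t) = a + R * sin(2*pi*t/period + phi)` to an
#' instantaneous-rate series driven by `I(t) = mean + A * sin(2*pi*t/period)`.
#' The gain is `R / A` in (spikes/s)/nA and the phase lead `phi` is positive
#' when the rate leads the current — the signature of a fractional
#' differentiator, whose log-log gain-versus-period slope equals minus the
#' fractional exponent.
#'
#' @param rate data frame from [instantaneous_rate()].
#' @param period stimulus period (ms).
#' @param current_amplitude sine amplitude A (nA).
#' @param n_discard_cycles initial cycles dropped as transient.
#' @param min_cycles minimum analyzable cycles after the discard.
#' @return List of class `"gain_phase"`: `period_ms`, `gain`,
#'   `phase_deg`, `residual` (RMS), `n_points`.
#' @export
gain_phase_at_period <- function(rate, period, current_amplitude,
                                 n_discard_cycles = 1, min_cycles = 3) {
  t0 <- n_discard_cycles * period
  d <- rate[rate$time_ms >= t0, ]
  span <- if (nrow(d)) diff(range(d$time_ms)) else 0
  if (span < min_cycles * period) {
    stop(sprintf("need >= %g analyzable cycles after discarding %g",
                 min_cycles, n_discard_cycles), call. = FALSE)
  }
  if (nrow(d) < 8 * min_cycles) {
    stop("too few spikes per cycle for a stable sinusoidal fit", call. = FALSE)
  }
  om <- 2 * pi / period
  X <- cbind(s = sin(om * d$time_ms), c = cos(om * d$time_ms))
  fit <- lm(d$rate_hz ~ X)
  b <- coef(fit)[["Xs"]]
  cc <- coef(fit)[["Xc"]]
  structure(list(period_ms = period,
                 gain = sqrt(b^2 + cc^2) / current_amplitude,
                 phase_deg = atan2(cc, b) * 180 / pi,
                 residual = sqrt(mean(fit$residuals^2)),
                 n_points = nrow(d)),
            class = "gain_phase")
}

#' @export
print.gain_phase <- function(x, ...) {
  cat(sprintf(
    "gain %.4g (spikes/s)/nA, phase lead %.3g deg at period %g ms (rms %.3g)\n",
    x$gain, x$phase_deg, x$period_ms, x$residual))
  invisible(x)
}

#' Single-exponential fit to an adaptation transient
#'
#' Fits `r(t) = r_inf + (r_0 - r_inf) * exp(-(t - t_start)/tau)` to the
#' firing-rate transient inside a window (typically one half-period of a
#' square-wave drive). `direction = "downward"` is the relaxation after an
#' upward input step (rate decays toward `r_inf`); `"upward"` after a
#' downward step.
#'
#' @param rate data frame from [instantaneous_rate()].
#' @param window `c(start, end)` (ms) containing a monotone transient.
#' @param direction `"downward"` or `"upward"`.
#' @return List of class `"adaptation_fit"`: `direction`, `tau_ms`, `r_0`,
#'   `r_inf`, `window`, `residual` (RMS).
#' @export
fit_adaptation_tau <- function(rate, window,
                               direction = c("downward", "upward")) {
  direction <- match.arg(direction)
  d <- rate[rate$time_ms >= window[1] & rate$time_ms <= window[2], ]
  if (nrow(d) < 5) stop("too few rate points in the window", call. = FALSE)
  tt <- d$time_ms - window[1]
  r <- d$rate_hz
  start <- list(rinf = mean(tail(r, max(3, nrow(d) %/% 5))),
                r0 = r[1],
                tau = diff(window) / 5)
  fit <- tryCatch(
    nls(r ~ rinf + (r0 - rinf) * exp(-tt / tau), start = start,
        algorithm = "port",
        lower = c(rinf = 0, r0 = 0, tau = 1e-3),
        control = list(warnOnly = FALSE)),
    error = function(e) {
      if (requireNamespace("minpack.lm", quietly = TRUE)) {
        minpack.lm::nlsLM(r ~ rinf + (r0 - rinf) * exp(-tt / tau),
                          start = start,
                          lower = c(0, 0, 1e-3))
      } else {
        stop(sprintf("adaptation fit did not converge: %s",
                     conditionMessage(e)), call. = FALSE)
      }
    })
  cf <- coef(fit)
  structure(list(direction = direction, tau_ms = unname(cf[["tau"]]),
                 r_0 = unname(cf[["r0"]]), r_inf = unname(cf[["rinf"]]),
                 window = window,
                 residual = sqrt(mean(residuals(fit)^2))),
            class = "adaptation_fit")
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat(sprintf("%s adaptation: tau = %.4g ms (r0 %.3g -> rinf %.3g, rms %.3g)\n",
              x$direction, x$tau_ms, x$r_0, x$r_inf, x$residual))
  invisible(x)
}

#' Power-law versus exponential fit of an ISI histogram
#'
#' Bins the inter-spike intervals logarithmically (default 10 bins per
#' decade), regresses log10(count) on log10(ISI) over occupied bins, and
#' also fits the exponential alternative (log10(count) on ISI) on the same
#' support so the two models can be compared by R-squared. A power-law ISI
#' distribution — the fractional-model signature at low exponents — shows as
#' a straight log-log line beating the exponential fit.
#'
#' @param isis data frame from [extract_isis()] or a numeric vector (ms).
#' @param bins_per_decade logarithmic binning density.
#' @return List of class `"powerlaw_fit"`: `slope`, `intercept`,
#'   `r_squared`, `r_squared_exp`, `n_bins`, `bin_centers`, `counts`.
#' @export
isi_powerlaw_fit <- function(isis, bins_per_decade = 10) {
  x <- if (is.data.frame(isis)) isis$isi_ms else as.numeric(isis)
  if (length(x) < 20) {
    stop("need at least 20 inter-spike intervals", call. = FALSE)
  }
  lo <- floor(log10(min(x)) * bins_per_decade) / bins_per_decade
  hi <- ceiling(log10(max(x)) * bins_per_decade) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  brk <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE),
                  nbins = length(brk) - 1)
  ctr <- sqrt(brk[-length(brk)] * brk[-1])
  occ <- cnt > 0
  if (sum(occ) < 2) {
    stop("fewer than 2 occupied histogram bins: no spread to fit",
         call. = FALSE)
  }
  lx <- log10(ctr[occ]); ly <- log10(cnt[occ])
  pl <- lm(ly ~ lx)
  ex <- lm(ly ~ ctr[occ])
  structure(list(slope = unname(coef(pl)[2]),
                 intercept = unname(coef(pl)[1]),
                 r_squared = summary(pl)$r.squared,
                 r_squared_exp = summary(ex)$r.squared,
                 n_bins = sum(occ), bin_centers = ctr[occ],
                 counts = cnt[occ]),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "log-log ISI fit: slope %.3g, R^2 %.3f (exponential R^2 %.3f, %d bins)\n",
    x$slope, x$r_squared, x$r_squared_exp, x$n_bins))
  invisible(x)
}

#' Correlation-based spike-time reliability across trials
#'
#' Each train is binarized on a common grid over the analysis epoch,
#' smoothed with a Gaussian kernel, and the reliability is the mean pairwise
#' normalized inner product
#' `R = 2 / (N (N-1)) * sum_{i<j} <s_i, s_j> / (|s_i| |s_j|)`,
#' ranging from 0 (no timing overlap at the smoothing scale) to 1 (identical
#' trains). Trains with no spikes in the epoch are excluded with a warning.
#'
#' @param trains list of spike-time vectors (ms), one per trial.
#' @param smoothing_sigma Gaussian kernel standard deviation (ms).
#' @param dt grid step for binarization (ms).
#' @param epoch `c(start, end)` analysis window (ms); `NULL` spans all
#'   trains.
#' @return List of class `"reliability"`: `R`, `n_trials` (after
#'   exclusions), `smoothing_sigma`, `epoch`.
#' @export
reliability <- function(trains, smoothing_sigma = 3, dt = 1, epoch = NULL) {
  stopifnot(is.list(trains), length(trains) >= 2)
  if (is.null(epoch)) epoch <- c(0, max(unlist(trains), 0) + dt)
  use <- vapply(trains, function(s)
    sum(s >= epoch[1] & s <= epoch[2]) > 0, logical(1))
  if (!all(use)) {
    warning(sprintf("%d train(s) with no spikes in the epoch excluded",
                    sum(!use)), call. = FALSE)
  }
  trains <- trains[use]
  if (length(trains) < 2) {
    stop("fewer than 2 trains with spikes in the epoch", call. = FALSE)
  }
  nb <- as.integer(ceiling(diff(epoch) / dt))
  half <- as.integer(ceiling(4 * smoothing_sigma / dt))
  kern <- exp(-((-half:half) * dt)^2 / (2 * smoothing_sigma^2))
  smooth1 <- function(s) {
    s <- s[s >= epoch[1] & s <= epoch[2]]
    b <- tabulate(pmin(nb, pmax(1L, as.integer(
      floor((s - epoch[1]) / dt) + 1L))), nbins = nb)
    as.numeric(convolve(c(rep(0, half), b, rep(0, half)), kern,
                        type = "filter"))
  }
  sm <- lapply(trains, smooth1)
  N <- length(sm)
  tot <- 0
  for (i in seq_len(N - 1)) {
    for (j in seq(i + 1, N)) {
      tot <- tot + sum(sm[[i]] * sm[[j]]) /
        (sqrt(sum(sm[[i]]^2)) * sqrt(sum(sm[[j]]^2)))
    }
  }
  structure(list(R = 2 * tot / (N * (N - 1)), n_trials = N,
                 smoothing_sigma = smoothing_sigma, epoch = epoch),
            class = "reliability")
}

#' @export
print.reliability <- function(x, ...) {
  cat(sprintf("spike-time reliability R = %.4f (%d trials, sigma %g ms)\n",
              x$R, x$n_trials, x$smoothing_sigma))
  invisible(x)
}

#' Silent period after a strong current pulse
#'
#' Time from the end of a pulse to the next spike. In the fractional model
#' the recent high-rate trajectory leaves a depolarizing-history memory
#' trace that suppresses firing after the pulse, so the pause grows with the
#' pulse amplitude until the refractory-bounded firing rate saturates it.
#'
#' @inheritParams extract_isis
#' @param pulse_end pulse offset time (ms).
#' @param t_max end of the simulated span (ms), used when no further spike
#'   occurs.
#' @return List: `pause_ms` and `censored` (`TRUE` if no spike followed the
#'   pulse within the simulation, in which case `pause_ms` is the time to
#'   the end of the span).
#' @export
pause_after_pulse <- function(spikes, pulse_end, t_max = NULL) {
  if (!any(spikes <= pulse_end)) {
    stop("no spiking activity before the pulse end", call. = FALSE)
  }
  nxt <- spikes[spikes > pulse_end]
  if (length(nxt) == 0) {
    if (is.null(t_max)) stop("no spike after the pulse and no `t_max` given",
                             call. = FALSE)
    return(list(pause_ms = t_max - pulse_end, censored = TRUE))
  }
  list(pause_ms = nxt[1] - pulse_end, censored = FALSE)
}

#' Cycle-to-cycle adaptation recovery ratio
#'
#' For the five-cycle step protocol: the ratio of the second-to-last
#' inter-spike interval of the last cycle to that of the first cycle. A
#' ratio near 1 means the adaptation state recovered across the
#' inter-stimulus gap; with short gaps the accumulated memory keeps the last
#' cycle pre-adapted and the ratio stays away from 1.
#'
#' @param isis_by_cycle list of ISI vectors (ms), one per cycle, in order.
#' @param first,last cycle indices compared (defaults 1 and the last).
#' @return `second-to-last ISI of the last cycle / second-to-last ISI of the
#'   first cycle`.
#' @export
cycle_recovery_metric <- function(isis_by_cycle, first = 1,
                                  last = length(isis_by_cycle)) {
  grab <- function(i) {
    x <- isis_by_cycle[[i]]
    if (is.data.frame(x)) x <- x$isi_ms
    if (length(x) < 3) {
      stop(sprintf("cycle %d has fewer than 3 inter-spike intervals", i),
           call. = FALSE)
    }
    x[length(x) - 1]
  }
  grab(last) / grab(first)
}
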