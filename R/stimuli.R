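#' Declarative injected-current stimulus specifications
#'
#' Constructors for the stimulation protocols used with the FLIF model. Each
#' returns a `"flif_stimulus"` object (a tagged list) that [render_stimulus()]
#' turns into a current sample sequence on a uniform time grid. All
#' generators are pure functions of (spec, grid, seed): noisy variants carry
#' an explicit seed and reproduce bitwise under it.
#'
#' * `stim_step()`: baseline, then a constant step of `amplitude` nA from
#'   `onset` for `duration` ms (the rest of the grid by default).
#' * `stim_pre_post()`: a conditioning epoch (hyper- or depolarizing,
#'   `pre_amplitude` nA for `pre_duration` ms) followed by a test step of
#'   `post_amplitude` nA to the end of the grid.
#' * `stim_sine()`: `mean + amplitude * sin(2*pi*t/period)`.
#' * `stim_square()`: alternating half-periods at `low` and `high` nA
#'   (starting low), each exactly `period/2` ms.
#' * `stim_zap()`: constant-amplitude sinusoid whose instantaneous frequency
#'   follows a sigmoid of time from `f_lo` to `f_hi` Hz over
#'   `sweep_duration` ms; the phase is the running integral of the
#'   instantaneous frequency, so there are no phase jumps. `steepness` scales
#'   the logistic slope; at 1 the endpoints are within 1% of `f_lo`/`f_hi`.
#' * `stim_noisy()`: Gaussian white noise (per-sample at the grid rate),
#'   scaled per-epoch by `variance_schedule` if given, alpha-filtered with
#'   time constant `tau_filter`, and added to `mean`.
#' * `stim_embedded()`: `mean` plus trial-varying intrinsic noise
#'   (`sigma_intrinsic`, seeded by `seed`) plus a frozen embedded noisy
#'   signal (`sigma_signal`, seeded by `seed_signal`), both alpha-filtered.
#'
#' Epoch durations that are not multiples of the time step are rounded down
#' to whole samples with a warning.
#'
#' @param amplitude,mean,low,high,pre_amplitude,post_amplitude current levels (nA).
#' @param onset,duration,pre_duration,period,sweep_duration times (ms).
#' @param baseline current outside the step (nA).
#' @param f_lo,f_hi sweep bounds (Hz).
#' @param steepness logistic slope multiplier for the ZAP sweep.
#' @param sigma,sigma_intrinsic,sigma_signal per-sample white-noise standard
#'   deviations (nA) before filtering.
#' @param tau_filter alpha-function filter time constant (ms).
#' @param seed,seed_signal integer seeds.
#' @param variance_schedule optional list of `c(duration_ms, sigma_nA)`
#'   epochs; must tile the grid.
#' @return A `"flif_stimulus"` specification.
#' @name stimulus
NULL

new_stimulus <- function(variant, ...) {
  structure(list(variant = variant, ...), class = "flif_stimulus")
}

#' @rdname stimulus
#' @export
stim_step <- function(amplitude, onset = 0, duration = Inf, baseline = 0) {
  if (onset < 0 || duration < 0) stop("durations must be >= 0", call. = FALSE)
  new_stimulus("step", amplitude = amplitude, onset = onset,
               duration = duration, baseline = baseline)
}

#' @rdname stimulus
#' @export
stim_pre_post <- function(pre_amplitude, pre_duration, post_amplitude) {
  if (pre_duration < 0) stop("durations must be >= 0", call. = FALSE)
  new_stimulus("pre_post", pre_amplitude = pre_amplitude,
               pre_duration = pre_duration, post_amplitude = post_amplitude)
}

#' @rdname stimulus
#' @export
stim_sine <- function(amplitude, period, mean = 0) {
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  new_stimulus("sine", amplitude = amplitude, period = period, mean = mean)
}

#' @rdname stimulus
#' @export
stim_square <- function(low, high, period) {
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  new_stimulus("square", low = low, high = high, period = period)
}

#' @rdname stimulus
#' @export
stim_zap <- function(amplitude, f_lo = 0, f_hi = 100, sweep_duration = 10000,
                     steepness = 1) {
  if (f_lo < 0 || f_hi < 0) stop("frequencies must be >= 0", call. = FALSE)
  if (f_lo > f_hi) stop("`f_lo` must not exceed `f_hi`", call. = FALSE)
  if (sweep_duration <= 0) stop("`sweep_duration` must be positive", call. = FALSE)
  new_stimulus("zap", amplitude = amplitude, f_lo = f_lo, f_hi = f_hi,
               sweep_duration = sweep_duration, steepness = steepness)
}

#' @rdname stimulus
#' @export
stim_noisy <- function(mean, sigma, tau_filter = 2, seed = 1,
                       variance_schedule = NULL) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (tau_filter <= 0) stop("`tau_filter` must be positive", call. = FALSE)
  new_stimulus("noisy", mean = mean, sigma = sigma, tau_filter = tau_filter,
               seed = seed, variance_schedule = variance_schedule)
}

#' @rdname stimulus
#' @export
stim_embedded <- function(mean, sigma_intrinsic, sigma_signal,
                          tau_filter = 2, seed = 1, seed_signal = 1000) {
  if (sigma_intrinsic < 0 || sigma_signal < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  new_stimulus("embedded", mean = mean, sigma_intrinsic = sigma_intrinsic,
               sigma_signal = sigma_signal, tau_filter = tau_filter,
               seed = seed, seed_signal = seed_signal)
}

#' @export
print.flif_stimulus <- function(x, ...) {
  flds <- x[setdiff(names(x), "variant")]
  flds <- flds[!vapply(flds, is.null, logical(1))]
  cat(sprintf("FLIF stimulus <%s>: %s\n", x$variant,
              paste(names(flds), vapply(flds, function(v)
                paste(format(unlist(v)), collapse = ","), character(1)),
                sep = "=", collapse = ", ")))
  invisible(x)
}

ms_to_samples <- function(ms, dt, what = "duration") {
  k <- ms / dt
  if (abs(k - round(k)) > 1e-9) {
    warning(sprintf("%s %g ms is not a multiple of dt = %g ms; rounded down",
                    what, ms, dt), call. = FALSE)
    k <- floor(k)
  }
  as.integer(round(k))
}

#' Render a stimulus specification onto a time grid
#'
#' @param spec a `"flif_stimulus"` from the [stimulus] constructors.
#' @param n_steps number of samples to render; sample `k` is the current over
#'   `[(k-1)*dt, k*dt)`.
#' @param dt time step (ms).
#' @return Numeric vector of `n_steps` current samples (nA), free of
#'   NA/Inf.
#' @examples
#' render_stimulus(stim_step(3), n_steps = 10, dt = 0.1)
#' @export
render_stimulus <- function(spec, n_steps, dt) {
  stopifnot(inherits(spec, "flif_stimulus"))
  if (n_steps < 1 || dt <= 0) stop("invalid grid", call. = FALSE)
  n <- as.integer(n_steps)
  t <- (seq_len(n) - 1) * dt            # time at the start of each step
  out <- switch(spec$variant,
    step = {
      i0 <- ms_to_samples(spec$onset, dt, "onset")
      ndur <- if (is.finite(spec$duration)) {
        ms_to_samples(spec$duration, dt)
      } else n
      x <- rep(spec$baseline, n)
      idx <- seq_len(n) > i0 & seq_len(n) <= i0 + ndur
      x[idx] <- spec$amplitude
      x
    },
    pre_post = {
      npre <- ms_to_samples(spec$pre_duration, dt)
      c(rep(spec$pre_amplitude, min(npre, n)),
        rep(spec$post_amplitude, max(n - npre, 0)))
    },
    sine = spec$mean + spec$amplitude * sin(2 * pi * t / spec$period),
    square = {
      half <- ms_to_samples(spec$period / 2, dt, "half-period")
      phase <- ((seq_len(n) - 1) %/% half) %% 2
      ifelse(phase == 0, spec$low, spec$high)
    },
    zap = zap_current(n, dt, spec$amplitude, spec$f_lo, spec$f_hi,
                      spec$sweep_duration, spec$steepness),
    noisy = noisy_current(n, dt, spec$mean, spec$sigma, spec$tau_filter,
                          spec$seed, spec$variance_schedule),
    embedded = {
      signal <- with_seed(spec$seed_signal,
                          rnorm(n, 0, spec$sigma_signal))
      intrinsic <- with_seed(spec$seed, rnorm(n, 0, spec$sigma_intrinsic))
      spec$mean + alpha_filter(signal, spec$tau_filter, dt) +
        alpha_filter(intrinsic, spec$tau_filter, dt)
    },
    stop(sprintf("unknown stimulus variant '%s'", spec$variant), call. = FALSE)
  )
  stopifnot(all(is.finite(out)))
  out
}

#' ZAP (frequency-sweep) current samples
#'
#' Sinusoid whose instantaneous frequency follows a logistic sigmoid of time
#' from `f_lo` to `f_hi` Hz over `sweep_duration`; the phase accumulates the
#' instantaneous frequency so the waveform is continuous. Beyond the sweep
#' the frequency stays at `f_hi`.
#'
#' @inheritParams render_stimulus
#' @inheritParams stimulus
#' @export
zap_current <- function(n_steps, dt, amplitude, f_lo = 0, f_hi = 100,
                        sweep_duration = 10000, steepness = 1) {
  n <- as.integer(n_steps)
  t <- (seq_len(n) - 1) * dt
  if (f_hi == f_lo) {
    f_inst <- rep(f_lo, n)
  } else {
    # logistic reaching within 1% of the endpoints at steepness = 1
    k <- steepness * 2 * log(99) / sweep_duration
    s <- 1 / (1 + exp(-k * (pmin(t, sweep_duration) - sweep_duration / 2)))
    f_inst <- f_lo + (f_hi - f_lo) * s
  }
  phase <- 2 * pi * cumsum(f_inst) * dt / 1000   # f in Hz, t in ms
  amplitude * sin(phase)
}

#' Causal alpha-function filter
#'
#' Convolves a signal with the normalized alpha kernel
#' `h(t) = (t / tau^2) * exp(-t / tau)` (unit area, peak at `t = tau`),
#' treating the pre-signal past as zero. Used to low-pass the white-noise
#' stimuli.
#'
#' @param signal numeric sample vector.
#' @param tau kernel time constant (ms), positive.
#' @param dt time step (ms).
#' @return Filtered signal, same length as the input.
#' @export
alpha_filter <- function(signal, tau, dt) {
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  m <- max(2L, as.integer(ceiling(12 * tau / dt)))
  tk <- (seq_len(m) - 1) * dt
  h <- (tk / tau^2) * exp(-tk / tau)
  h <- h / sum(h)                       # exact unit gain on the grid
  n <- length(signal)
  y <- stats::filter(c(rep(0, m - 1), signal), h, sides = 1)
  as.numeric(y[(m - 1) + seq_len(n)])
}

#' Alpha-filtered Gaussian noise current
#'
#' Per-sample Gaussian white noise (generated at the grid rate), optionally
#' scaled per-epoch by a variance schedule, alpha-filtered, and added to a
#' mean level. Identical seeds give bitwise-identical sequences.
#'
#' @inheritParams render_stimulus
#' @inheritParams stimulus
#' @export
noisy_current <- function(n_steps, dt, mean, sigma, tau_filter = 2,
                          seed = 1, variance_schedule = NULL) {
  n <- as.integer(n_steps)
  if (is.null(variance_schedule)) {
    sig <- rep(sigma, n)
  } else {
    lens <- vapply(variance_schedule, function(e)
      ms_to_samples(e[[1]], dt), integer(1))
    if (sum(lens) < n) {
      stop("variance schedule does not cover the grid", call. = FALSE)
    }
    sig <- rep(vapply(variance_schedule, function(e) e[[2]], numeric(1)),
               times = lens)[seq_len(n)]
  }
  noise <- with_seed(seed, rnorm(n)) * sig
  mean + alpha_filter(noise, tau_filter, dt)
}

# Evaluate expr under a local RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
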