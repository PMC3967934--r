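#' Mittag-Leffler function E_alpha(z) for real arguments
#'
#' Evaluates the one-parameter Mittag-Leffler function
#' `E_alpha(z) = sum_k z^k / Gamma(alpha k + 1)`, the relaxation function of
#' fractional-order linear systems (`E_1(z) = exp(z)`). Negative real
#' arguments are the use case: they govern the sub-threshold voltage
#' relaxation of the fractional membrane.
#'
#' For `|z| < 1` the power series is summed directly. For `z <= -1` the
#' alternating series loses precision catastrophically (its largest terms
#' grow much faster than the result), so the completely monotone spectral
#' representation
#' `E_alpha(-x) = sin(alpha*pi)/(pi*alpha) *`
#' `integral_0^Inf exp(-(u*x)^(1/alpha)) / (u^2 + 2*u*cos(alpha*pi) + 1) du`
#' is integrated numerically instead; the two branches agree on an overlap
#' band (verified in the test suite). Large positive arguments fall back to
#' the series and error if it fails to converge.
#'
#' @param alpha order in (0, 1].
#' @param z real argument (vectorized).
#' @param tol absolute tolerance of the evaluation.
#' @return `E_alpha(z)`, same length as `z`.
#' @examples
#' mittag_leffler(1, -1)      # exp(-1)
#' mittag_leffler(0.5, -2)    # exp(4) * erfc(2)
#' @export
mittag_leffler <- function(alpha, z, tol = 1e-10) {
  check_alpha(alpha)
  vapply(z, function(zi) ml_scalar(alpha, zi, tol), numeric(1))
}

ml_scalar <- function(alpha, z, tol) {
  if (!is.finite(z)) stop("`z` must be finite", call. = FALSE)
  if (alpha == 1) return(exp(z))
  if (z == 0) return(1)
  if (z > -1) return(ml_series(alpha, z, tol))
  ml_integral(alpha, -z, tol)
}

ml_series <- function(alpha, z, tol, kmax = 2000L) {
  s <- 1
  term <- 1
  for (k in seq_len(kmax)) {
    term <- term * z / exp(lgamma(alpha * k + 1) - lgamma(alpha * (k - 1) + 1))
    s <- s + term
    if (abs(term) < tol && k > 2 / alpha) return(s)
  }
  stop(sprintf("Mittag-Leffler series did not converge (alpha = %g, z = %g)",
               alpha, z), call. = FALSE)
}

ml_integral <- function(alpha, x, tol) {
  stopifnot(x > 0)
  f <- function(u) {
    exp(-(u * x)^(1 / alpha)) / (u^2 + 2 * u * cos(alpha * pi) + 1)
  }
  val <- tryCatch(
    integrate(f, 0, Inf, rel.tol = min(tol, 1e-10), abs.tol = tol,
              subdivisions = 400L)$value,
    error = function(e) {
      stop(sprintf("Mittag-Leffler quadrature failed (alpha = %g, z = %g): %s",
                   alpha, -x, conditionMessage(e)), call. = FALSE)
    })
  sin(alpha * pi) / (pi * alpha) * val
}

#' Closed-form sub-threshold voltage under constant current
#'
#' The analytic solution of the fractional membrane equation for constant
#' current and no spiking:
#' `V(t) = V_inf + (V_0 - V_inf) * E_alpha(-t^alpha / tau_m)` with the
#' steady state `V_inf = V_L + I / g_L`. At `alpha = 1` this is the classical
#' exponential charging curve; for `alpha < 1` the relaxation is
#' Mittag-Leffler, with a power-law tail slower than any exponential. This
#' closed form is the numerical oracle for the L1 integrator.
#'
#' @param t time(s) since current onset (ms), vectorized.
#' @param I constant current (nA).
#' @param params a [flif_params()] object; `V_0` is the starting voltage.
#' @param v_start override of the starting voltage (mV), default `params$V_0`.
#' @param tol Mittag-Leffler tolerance.
#' @return Voltage (mV) at each `t`.
#' @export
subthreshold_voltage <- function(t, I, params, v_start = params$V_0,
                                 tol = 1e-10) {
  stopifnot(inherits(params, "flif_params"), all(t >= 0))
  v_inf <- params$V_L + I / params$g_L
  a <- params$alpha
  v_inf + (v_start - v_inf) *
    mittag_leffler(a, -t^a / params$tau_m, tol = tol)
}

#' Small-time approximation of the sub-threshold voltage
#'
#' Truncates the Mittag-Leffler relaxation to its first two series terms,
#' `E_alpha(-t^alpha/tau_m) ~ 1 - t^alpha / (tau_m * Gamma(1 + alpha))`,
#' valid for `t` small relative to the membrane time constant. It underlies
#' the closed-form spike time and firing-rate approximations; the full
#' evaluator is the default everywhere else, and the truncation diverges
#' from the true solution at large `t`.
#'
#' @inheritParams subthreshold_voltage
#' @export
subthreshold_voltage_smalltime <- function(t, I, params,
                                           v_start = params$V_0) {
  stopifnot(inherits(params, "flif_params"), all(t >= 0))
  v_inf <- params$V_L + I / params$g_L
  a <- params$alpha
  v_inf + (v_start - v_inf) * (1 - t^a / (params$tau_m * gamma(1 + a)))
}

#' Time for the voltage to charge from reset to threshold
#'
#' For a constant supra-threshold current, the time the analytic
#' (memory-reset) model takes to rise from `V_reset` to `V_th` and fire.
#' `method = "exact"` inverts the full Mittag-Leffler solution by
#' root-finding; `method = "smalltime"` uses the closed form from the
#' two-term truncation,
#' `T = (tau_m * Gamma(1+alpha) * (V_th - V_reset) / (V_inf - V_reset))^(1/alpha)`.
#' Sub-threshold currents (at or below `g_L * (V_th - V_L)`) never fire and
#' return `NA`.
#'
#' @param I constant current (nA).
#' @param params a [flif_params()] object.
#' @param method `"exact"` or `"smalltime"`.
#' @param v_start starting voltage (mV), default `params$V_reset`.
#' @return Charging time (ms), or `NA_real_` if the current cannot drive the
#'   voltage to threshold.
#' @examples
#' time_to_fire(3, flif_params(alpha = 1)) # 20 * log(1.2) ~ 3.646 ms
#' @export
time_to_fire <- function(I, params, method = c("exact", "smalltime"),
                         v_start = params$V_reset) {
  stopifnot(inherits(params, "flif_params"))
  method <- match.arg(method)
  v_inf <- params$V_L + I / params$g_L
  if (v_inf <= params$V_th) return(NA_real_)
  a <- params$alpha
  frac <- (params$V_th - v_start) / (v_inf - v_start)   # in (0, 1)
  if (method == "smalltime") {
    return((params$tau_m * gamma(1 + a) * frac)^(1 / a))
  }
  # solve E_alpha(-T^alpha / tau_m) = 1 - frac for s = T^alpha / tau_m
  target <- 1 - frac
  g <- function(s) mittag_leffler(a, -s) - target
  hi <- 1
  while (g(hi) > 0) hi <- hi * 2
  s <- uniroot(g, c(0, hi), tol = 1e-12)$root
  (s * params$tau_m)^(1 / a)
}

#' Approximate steady firing rate of the memory-reset model
#'
#' One spike per charging-plus-refractory cycle:
#' `1000 / (time_to_fire + tau_ref)` spikes/s, 0 for sub-threshold current.
#' The rate is bounded by `1000 / tau_ref` and increases continuously from
#' zero at the threshold current (Type I excitability).
#'
#' @inheritParams time_to_fire
#' @return Firing rate (spikes/s).
#' @export
firing_rate_approx <- function(I, params, method = c("exact", "smalltime")) {
  ttf <- time_to_fire(I, params, method = match.arg(method))
  if (is.na(ttf)) return(0)
  1000 / (ttf + params$tau_ref)
}

#' Spiking simulation of the analytic solution with memory reset
#'
#' Iterates the closed-form sub-threshold solution between spikes: after each
#' spike the voltage restarts at `V_reset` with a new time origin, so the
#' Mittag-Leffler memory is wiped at every reset and all inter-spike
#' intervals after the first are equal. This is the analytic counterpart of
#' [flif_simulate()] with `memory_mode = "reset_on_spike"`, and differs
#' qualitatively from the full-memory model, which keeps adapting.
#'
#' @param params a [flif_params()] object.
#' @param I constant current (nA).
#' @param duration simulated span (ms).
#' @param dt grid step for the returned voltage trace (ms).
#' @return List with `time`, `voltage` (clipped at `V_th` at spike samples,
#'   `V_reset` during refractory), and `spikes` (ms, continuous-time).
#' @export
simulate_analytic_reset <- function(params, I, duration, dt = 0.1) {
  stopifnot(inherits(params, "flif_params"), duration > 0)
  tg <- seq(0, duration, by = dt)
  v <- numeric(length(tg))
  spikes <- numeric(0)

  t0 <- 0
  v0 <- params$V_0
  repeat {
    ttf <- time_to_fire(I, params, v_start = v0)
    cycle_end <- if (is.na(ttf)) Inf else t0 + ttf
    idx <- tg >= t0 & tg < min(cycle_end, duration + dt)
    v[idx] <- subthreshold_voltage(tg[idx] - t0, I, params, v_start = v0)
    if (!is.finite(cycle_end) || cycle_end > duration) break
    spikes <- c(spikes, cycle_end)
    ridx <- tg >= cycle_end & tg < cycle_end + params$tau_ref
    v[ridx] <- params$V_reset
    if (any(ridx)) v[which(ridx)[1]] <- params$V_th  # spike sample clipped
    t0 <- cycle_end + params$tau_ref
    v0 <- params$V_reset
    if (t0 > duration) break
  }
  list(time = tg, voltage = pmin(v, params$V_th), spikes = spikes)
}
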