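#' Simulate the fractional leaky integrate-and-fire neuron
#'
#' Integrates the Caputo fractional membrane equation
#' `C_m d^alpha V / dt^alpha = -g_L (V - V_L) + I(t)` with the explicit L1
#' scheme and a fire-and-reset rule: when the candidate voltage reaches the
#' threshold (inclusive), the spike sample records `V_th`, and the voltage is
#' clamped to `V_reset` for the refractory period. All samples, including the
#' clamped ones, enter the voltage history that feeds the memory trace, which
#' is what produces the post-reset negative memory transient and the
#' accumulation of adaptation across spikes. The first step is a
#' single-sample L1 step (no past increments exist yet), which at
#' `alpha = 1` is exactly a forward-Euler step.
#'
#' With `memory_mode = "reset_on_spike"` the history is truncated at each
#' spike, so the fractional integration restarts from the reset sample; under
#' constant current this variant fires regularly after the first spike,
#' whereas the full-memory model keeps adapting.
#'
#' The exact memory sum costs O(N) per step (O(N^2) per simulation); an
#' optional truncation window bounds the lookback but is off by default
#' because the model's long-range effects (multi-second recovery) live in the
#' full trace. `alpha = 1` short-circuits to the classical model in O(N).
#'
#' @param params a [flif_params()] object.
#' @param current numeric vector of injected current samples (nA);
#'   `current[k]` drives the update from `t_{k-1}` to `t_k`, so the voltage
#'   trace has `length(current) + 1` samples on `t = 0, dt, ..., n*dt`.
#' @param dt time step (ms); 0.1 ms is the default used throughout.
#' @param memory_mode `"full"` (integrate the entire history) or
#'   `"reset_on_spike"` (discard history at each spike).
#' @param trunc_window optional integer: limit the memory sum to the most
#'   recent `trunc_window` steps. `Inf` (default) disables truncation.
#' @return An object of class `"flif_sim"`: list with `time` (ms), `voltage`
#'   (mV), `current` (nA, aligned on the same grid; the sample at t = 0
#'   repeats the first value), `spikes` (ms), `memory_trace` and
#'   `markov_term` (mV, `NA` at t = 0), plus `dt`, `params`, `memory_mode`.
#' @examples
#' p <- flif_params(alpha = 0.2)
#' sim <- flif_simulate(p, rep(3, 5000), dt = 0.1)
#' length(sim$spikes)
#' @export
flif_simulate <- function(params, current, dt = 0.1,
                          memory_mode = c("full", "reset_on_spike"),
                          trunc_window = Inf) {
  stopifnot(inherits(params, "flif_params"))
  memory_mode <- match.arg(memory_mode)
  if (!is.numeric(current) || length(current) < 1 || anyNA(current)) {
    stop("`current` must be a numeric vector without missing values",
         call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a positive scalar", call. = FALSE)
  }
  tw <- if (is.finite(trunc_window)) as.integer(trunc_window) else -1L
  res <- .flif_simulate_cpp(as.numeric(current), dt,
                            params$C_m, params$g_L, params$V_L,
                            params$V_reset, params$V_0, params$V_th,
                            params$tau_ref, params$alpha,
                            memory_mode == "reset_on_spike", tw)
  n <- length(current)
  structure(list(
    time = seq(0, by = dt, length.out = n + 1),
    voltage = res$voltage,
    current = c(current[1], current),
    spikes = res$spikes,
    memory_trace = res$memory_trace,
    markov_term = res$markov_term,
    dt = dt,
    params = params,
    memory_mode = memory_mode
  ), class = "flif_sim")
}

#' @export
print.flif_sim <- function(x, ...) {
  cat(sprintf(
    "FLIF simulation: alpha = %g, dt = %g ms, %g ms span, %d spike(s), memory %s\n",
    x$params$alpha, x$dt, max(x$time), length(x$spikes), x$memory_mode))
  invisible(x)
}

#' @export
as.data.frame.flif_sim <- function(x, ...) {
  data.frame(time_ms = x$time,
             current_nA = x$current,
             voltage_mV = x$voltage,
             memory_trace_mV = x$memory_trace,
             markov_term_mV = x$markov_term)
}

# ---- Reference (pure R) stepper -------------------------------------------

#' Initialize a neuron state for step-by-step integration
#'
#' The R-level stepper mirrors the compiled simulator one step at a time; it
#' is the readable reference of the update rule and is cross-checked against
#' [flif_simulate()] in the test suite. State fields: the full voltage
#' history, refractory countdown (ms), spike times, and the active history
#' start (for the memory-reset variant).
#'
#' @param params a [flif_params()] object.
#' @return An object of class `"flif_state"`.
#' @export
flif_state_init <- function(params) {
  stopifnot(inherits(params, "flif_params"))
  structure(list(history = params$V_0, countdown = 0,
                 spikes = numeric(0), hist_start = 1L,
                 params = params),
            class = "flif_state")
}

#' Advance a neuron state by one time step
#'
#' One explicit L1 update: candidate
#' `V_N = (dt^alpha Gamma(2-alpha)/C_m) * (-g_L (V_{N-1} - V_L) + I) + V_{N-1}
#' - memory_trace`, with the single-sample L1 bootstrap when fewer than two
#' history samples exist, inclusive threshold crossing, and the refractory
#' clamp at `V_reset`.
#'
#' @param state a `"flif_state"` from [flif_state_init()].
#' @param I_now injected current over this step (nA).
#' @param dt time step (ms).
#' @param memory_mode `"full"` or `"reset_on_spike"`.
#' @return The updated state.
#' @export
flif_advance <- function(state, I_now, dt = 0.1,
                         memory_mode = c("full", "reset_on_spike")) {
  stopifnot(inherits(state, "flif_state"))
  memory_mode <- match.arg(memory_mode)
  p <- state$params
  h <- state$history
  N <- length(h)                       # computing sample index N (t = N*dt)
  v_prev <- h[N]
  drive <- (-p$g_L * (v_prev - p$V_L) + I_now) / p$C_m

  if (state$countdown > dt / 2) {
    state$history <- c(h, p$V_reset)
    state$countdown <- state$countdown - dt
    return(state)
  }

  active <- h[state$hist_start:N]
  if (length(active) < 2) {            # single-sample L1 bootstrap step
    cand <- v_prev + gamma_coefficient(p$alpha, dt) * drive
  } else {
    w <- memory_weights(p$alpha, length(active))
    M <- voltage_memory_trace(active, w)
    cand <- gamma_coefficient(p$alpha, dt) * drive + v_prev - M
  }
  if (!is.finite(cand)) {
    stop(sprintf("non-finite voltage candidate at step %d", N), call. = FALSE)
  }

  if (cand >= p$V_th) {
    state$history <- c(h, p$V_th)
    state$spikes <- c(state$spikes, N * dt)
    # the spike sample consumes one dt of the refractory clock; at least one
    # reset sample is always recorded
    state$countdown <- max(ceiling(p$tau_ref / dt) - 1, 1) * dt
    if (memory_mode == "reset_on_spike") state$hist_start <- N + 2L
  } else {
    state$history <- c(h, cand)
  }
  state
}
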