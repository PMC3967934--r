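#' L1 memory weights for past voltage increments
#'
#' The L1 discretization of a Caputo derivative of order `alpha` expresses it
#' as a weighted sum of past one-step voltage increments. At step `N` the
#' increment `V(t_{k+1}) - V(t_k)` (k = 0, ..., N-1) carries the weight
#' `(N-k)^(1-alpha) - (N-1-k)^(1-alpha)`. The most recent increment
#' (k = N-1) always has weight 1 and is absorbed into the explicit update;
#' this function returns the weights of the remaining k = 0, ..., N-2 past
#' increments, i.e. the kernel of the voltage-memory trace.
#'
#' At `alpha = 1` every past weight is exactly zero (the classical,
#' memoryless limit). For `alpha < 1` the weights are positive, decay as a
#' power law with lag, and grow pointwise as `alpha` decreases, which is how
#' the fractional model couples ever more strongly to its past.
#'
#' @param alpha fractional exponent in (0, 1].
#' @param N step index (the step being computed); must be at least 2 so that
#'   at least one past increment exists.
#' @return Numeric vector of length `N - 1`: weights for increments
#'   k = 0, ..., N-2 (oldest first).
#' @examples
#' memory_weights(0.5, 3) # lag-3 and lag-2 weights
#' @export
memory_weights <- function(alpha, N) {
  check_alpha(alpha)
  if (!is.numeric(N) || length(N) != 1 || N < 2 || N != round(N)) {
    stop("`N` must be an integer >= 2 (at least one past increment)",
         call. = FALSE)
  }
  k <- 0:(N - 2)
  (N - k)^(1 - alpha) - (N - 1 - k)^(1 - alpha)
}

#' Fractional coefficient of the Markov term
#'
#' The scalar `dt^alpha * Gamma(2 - alpha)` multiplying the instantaneous
#' (Markovian) drive in the L1-discretized voltage update. At `alpha = 1` it
#' reduces to `dt`, recovering the forward-Euler step of the classical model.
#' For `dt < 1` ms it grows as `alpha` decreases, strengthening the effect of
#' the input current on the voltage.
#'
#' @inheritParams memory_weights
#' @param dt time step (ms), positive.
#' @return A positive scalar (ms^alpha units, used consistently with the
#'   fixed internal unit system).
#' @export
gamma_coefficient <- function(alpha, dt) {
  check_alpha(alpha)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a positive scalar", call. = FALSE)
  }
  dt^alpha * gamma(2 - alpha)
}

#' Voltage-memory trace of a voltage history
#'
#' The weighted sum of past voltage increments that makes the fractional
#' model non-Markovian: `sum_k (V(t_{k+1}) - V(t_k)) * W(k)` over
#' k = 0, ..., N-2 for a history of N+1 samples. The weights are positive, so
#' the sign of the trace follows the sign of the recent voltage trajectory:
#' positive while the cell depolarizes (opposing further depolarization in
#' the update, which subtracts the trace) and transiently negative right
#' after a spike reset.
#'
#' @param history numeric vector of voltage samples (mV), oldest first,
#'   length >= 2; the last sample is V(t_{N-1}) of the step being computed.
#' @param weights weights from [memory_weights()] for the matching step
#'   index, i.e. `length(history) - 1` values.
#' @return The memory trace (mV).
#' @export
voltage_memory_trace <- function(history, weights) {
  if (length(history) < 2) {
    stop("`history` must contain at least 2 samples", call. = FALSE)
  }
  if (length(weights) != length(history) - 1) {
    stop(sprintf(
      "kernel/history mismatch: %d weights for %d increments",
      length(weights), length(history) - 1), call. = FALSE)
  }
  sum(diff(history) * weights)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must be a single number in (0, 1]", call. = FALSE)
  }
  invisible(alpha)
}
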