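#' Model parameters for the fractional leaky integrate-and-fire neuron
#'
#' Constructs a validated parameter set for the FLIF model. The internal unit
#' system is fixed to mV, ms, nA, nF and microsiemens, which is
#' self-consistent (nF * mV / ms = nA); leak conductances quoted in nS must
#' be given here in microsiemens (25 nS = 0.025 uS). The membrane time
#' constant `tau_m = C_m / g_L` (ms) is always derived, never stored
#' independently.
#'
#' Two presets are provided. `"table1"` is the standard set: C_m = 0.5 nF,
#' g_L = 0.025 uS (25 nS, tau_m = 20 ms), V_L = V_reset = V_0 = -70 mV,
#' V_th = -50 mV, tau_ref = 5 ms. `"adapted"` lowers the leak to
#' g_L = 0.005 uS (tau_m = 100 ms) and lengthens the refractory period to
#' 10 ms, the variant used for the oscillatory-drive, history-dependence and
#' noise protocols where slower membranes match cortical recordings.
#'
#' @param alpha fractional exponent of the voltage derivative, in (0, 1];
#'   1 recovers the classical leaky integrate-and-fire model.
#' @param preset `"table1"` or `"adapted"`; starting values overridable by the
#'   remaining arguments.
#' @param C_m membrane capacitance (nF).
#' @param g_L leak conductance (uS).
#' @param V_L leak reversal potential (mV).
#' @param V_reset post-spike reset potential (mV).
#' @param V_0 initial potential (mV).
#' @param V_th spike threshold (mV).
#' @param tau_ref absolute refractory period (ms).
#' @return An object of class `"flif_params"`: a list with the fields above
#'   plus the derived `tau_m` (ms).
#' @examples
#' p <- flif_params(alpha = 0.2)
#' p$tau_m # 20 ms
#' @export
flif_params <- function(alpha = 1,
                        preset = c("table1", "adapted"),
                        C_m = NULL, g_L = NULL, V_L = NULL,
                        V_reset = NULL, V_0 = NULL, V_th = NULL,
                        tau_ref = NULL) {
  preset <- match.arg(preset)
  base <- list(C_m = 0.5, g_L = 0.025, V_L = -70, V_reset = -70,
               V_0 = -70, V_th = -50, tau_ref = 5)
  if (preset == "adapted") {
    base$g_L <- 0.005
    base$tau_ref <- 10
  }
  for (nm in names(base)) {
    v <- get(nm)
    if (!is.null(v)) base[[nm]] <- v
  }
  p <- c(list(alpha = alpha), base)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must be a single number in (0, 1]", call. = FALSE)
  }
  if (p$C_m <= 0) stop("`C_m` must be positive", call. = FALSE)
  if (p$g_L <= 0) stop("`g_L` must be positive", call. = FALSE)
  if (p$tau_ref < 0) stop("`tau_ref` must be non-negative", call. = FALSE)
  if (p$V_reset >= p$V_th) stop("`V_reset` must lie below `V_th`", call. = FALSE)
  if (p$V_0 > p$V_th) stop("`V_0` must not exceed `V_th`", call. = FALSE)
  p$tau_m <- p$C_m / p$g_L
  structure(p, class = "flif_params")
}

#' @export
print.flif_params <- function(x, ...) {
  cat("Fractional leaky integrate-and-fire parameters\n")
  cat(sprintf("  alpha   = %-8g (fractional exponent)\n", x$alpha))
  cat(sprintf("  C_m     = %-8g nF\n", x$C_m))
  cat(sprintf("  g_L     = %-8g uS   (tau_m = %g ms)\n", x$g_L, x$tau_m))
  cat(sprintf("  V_L     = %-8g mV,  V_th = %g mV\n", x$V_L, x$V_th))
  cat(sprintf("  V_reset = %-8g mV,  V_0  = %g mV\n", x$V_reset, x$V_0))
  cat(sprintf("  tau_ref = %-8g ms\n", x$tau_ref))
  invisible(x)
}

#' Rheobase (threshold) current of the leaky membrane
#'
#' The constant current `g_L * (V_th - V_L)` below which the steady-state
#' voltage stays sub-threshold, 0.5 nA for the standard parameter set.
#'
#' @param params a [flif_params()] object.
#' @return Threshold current in nA.
#' @export
threshold_current <- function(params) {
  params$g_L * (params$V_th - params$V_L)
}
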