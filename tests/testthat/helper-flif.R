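# Shared fixtures: standard parameter sets and closed-form classical-LIF
# oracles used across the test files.

p_std <- function(alpha = 1, ...) flif_params(alpha = alpha, ...)

# classical LIF charging time from v0 to v1 under constant current I
lif_charge_time <- function(I, params, v0 = params$V_reset,
                            v1 = params$V_th) {
  v_inf <- params$V_L + I / params$g_L
  params$tau_m * log((v_inf - v0) / (v_inf - v1))
}

# classical LIF sub-threshold trajectory from V_0
lif_voltage <- function(t, I, params) {
  v_inf <- params$V_L + I / params$g_L
  v_inf + (params$V_0 - v_inf) * exp(-t / params$tau_m)
}

# steady inter-spike interval of the classical LIF
lif_isi <- function(I, params) params$tau_ref + lif_charge_time(I, params)

# evaluate expr under a seed, restoring the RNG state afterwards
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
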