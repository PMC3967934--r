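#' Write a simulation trace as CSV
#'
#' Columns `time_ms,current_nA,voltage_mV,memory_trace_mV,markov_term_mV`,
#' all floating-point values at 9 significant digits so that determinism
#' checks on the files are meaningful.
#'
#' @param sim a `"flif_sim"` object.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(sim, path) {
  df <- as.data.frame(sim)
  df[] <- lapply(df, function(col) signif(col, 9))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write spike times as CSV or JSON
#'
#' @param spikes numeric spike times (ms) or a `"flif_sim"` object.
#' @param path output file.
#' @param format `"csv"` (single column `spike_time_ms`) or `"json"` (array).
#' @return The path, invisibly.
#' @export
write_spikes <- function(spikes, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(spikes, "flif_sim")) spikes <- spikes$spikes
  s <- signif(as.numeric(spikes), 9)
  if (format == "csv") {
    write.csv(data.frame(spike_time_ms = s), path, row.names = FALSE,
              quote = FALSE)
  } else {
    jsonlite::write_json(s, path, digits = NA)
  }
  invisible(path)
}

#' Run configuration for a full simulation-plus-analysis protocol
#'
#' A run configuration bundles model parameters, a stimulus specification,
#' simulation options and the requested analyses, and round-trips
#' losslessly through the YAML config format ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param params a [flif_params()] object.
#' @param stimulus a `"flif_stimulus"` object.
#' @param duration_ms simulated span (ms).
#' @param dt time step (ms).
#' @param memory_mode `"full"` or `"reset_on_spike"`.
#' @param analyses character vector among `"isis"`, `"rate"`, `"latency"`,
#'   `"mean_rate"`.
#' @param seed integer seed recorded with the run.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(params, stimulus, duration_ms, dt = 0.1,
                       memory_mode = "full",
                       analyses = c("isis", "rate", "latency"),
                       seed = 1) {
  stopifnot(inherits(params, "flif_params"),
            inherits(stimulus, "flif_stimulus"),
            duration_ms > 0, dt > 0,
            memory_mode %in% c("full", "reset_on_spike"))
  structure(list(params = params, stimulus = stimulus,
                 duration_ms = duration_ms, dt = dt,
                 memory_mode = memory_mode, analyses = analyses,
                 seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `"run_config"`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    model = unclass(config$params)[c("alpha", "C_m", "g_L", "V_L", "V_reset",
                                     "V_0", "V_th", "tau_ref")],
    stimulus = unclass(config$stimulus),
    simulation = list(duration_ms = config$duration_ms, dt = config$dt,
                      memory_mode = config$memory_mode,
                      seed = config$seed),
    analyses = as.list(config$analyses))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("model", "stimulus", "simulation")) {
    if (is.null(x[[f]])) stop(sprintf("config is missing section '%s'", f),
                              call. = FALSE)
  }
  params <- do.call(flif_params, x$model)
  stim <- x$stimulus
  variant <- stim$variant
  stim$variant <- NULL
  if (!is.null(stim$variance_schedule)) {
    stim$variance_schedule <- lapply(stim$variance_schedule, unlist)
  }
  ctor <- switch(variant,
                 step = stim_step, pre_post = stim_pre_post,
                 sine = stim_sine, square = stim_square, zap = stim_zap,
                 noisy = stim_noisy, embedded = stim_embedded,
                 stop(sprintf("unknown stimulus variant '%s'", variant),
                      call. = FALSE))
  run_config(params, do.call(ctor, stim),
             duration_ms = x$simulation$duration_ms,
             dt = x$simulation$dt,
             memory_mode = x$simulation$memory_mode %||% "full",
             analyses = unlist(x$analyses) %||% character(0),
             seed = x$simulation$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a run configuration and write its artifacts
#'
#' Simulates the configured protocol and writes the trace CSV, spike CSV
#' and an analysis JSON into `out_dir`. Deterministic: the same
#' configuration (including seed) produces byte-identical files.
#'
#' @param config a [run_config()] (or a path to a YAML config).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress the log line.
#' @return Named list of written paths, invisibly.
#' @export
run_protocol <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- as.integer(round(config$duration_ms / config$dt))
  t_start <- proc.time()[["elapsed"]]
  current <- render_stimulus(config$stimulus, n, config$dt)
  sim <- flif_simulate(config$params, current, dt = config$dt,
                       memory_mode = config$memory_mode)

  paths <- list(trace = file.path(out_dir, "trace.csv"),
                spikes = file.path(out_dir, "spikes.csv"),
                analysis = file.path(out_dir, "analysis.json"))
  write_trace_csv(sim, paths$trace)
  write_spikes(sim, paths$spikes)

  out <- list(n_spikes = length(sim$spikes))
  if ("isis" %in% config$analyses) {
    out$isis_ms <- signif(suppressWarnings(extract_isis(sim$spikes))$isi_ms, 9)
  }
  if ("rate" %in% config$analyses) {
    r <- instantaneous_rate(sim$spikes)
    out$rate <- list(time_ms = signif(r$time_ms, 9),
                     rate_hz = signif(r$rate_hz, 9))
  }
  if ("latency" %in% config$analyses) {
    out$first_spike_latency_ms <- first_spike_latency(sim$spikes)
  }
  if ("mean_rate" %in% config$analyses) {
    out$mean_rate_hz <- mean_rate(sim$spikes, config$duration_ms / 2,
                                  config$duration_ms)
  }
  jsonlite::write_json(out, paths$analysis, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!quiet) {
    message(sprintf(
      "INFO run_protocol: alpha=%g dt=%g ms seed=%d runtime=%.2fs -> %s",
      config$params$alpha, config$dt, config$seed,
      proc.time()[["elapsed"]] - t_start, out_dir))
  }
  invisible(paths)
}

#' Named protocol presets
#'
#' Ready-made [run_config()]s for the standard study protocols: `fig1-step`
#' (constant step), `fig2-prepost` (conditioning then test step),
#' `fig3-zap`, `fig3-sine`, `fig3-square`, `fig4-cycles` (five-cycle gap),
#' `fig4-pulse` (pause after pulse), `fig5-variance` (variance-switching
#' noise), `fig6-reliability` (noisy drive for reliability ensembles),
#' `fig9-compare` (memory-reset comparison).
#'
#' @param name preset name.
#' @param alpha fractional exponent override.
#' @param seed seed override.
#' @return A `"run_config"`.
#' @export
flif_protocol <- function(name, alpha = NULL, seed = 1) {
  std <- function(a) flif_params(alpha = a %||% 0.2)
  adapted <- function(a, def = 0.2)
    flif_params(alpha = a %||% def, preset = "adapted")
  switch(name,
    "fig1-step" = run_config(std(alpha), stim_step(3), 1000, dt = 0.1,
                             seed = seed),
    "fig2-prepost" = run_config(std(alpha), stim_pre_post(-3, 1000, 3),
                                4000, dt = 0.1, seed = seed),
    "fig3-zap" = run_config(std(alpha), stim_zap(0.1), 10000, dt = 0.1,
                            analyses = character(0), seed = seed),
    "fig3-sine" = run_config(adapted(alpha),
                             stim_sine(0.3, 4000, mean = 2.5), 12000,
                             dt = 0.5, seed = seed),
    "fig3-square" = run_config(adapted(alpha),
                               stim_square(3.4, 4, 16000), 32000, dt = 0.5,
                               seed = seed),
    "fig4-cycles" = run_config(adapted(alpha),
                               stim_square(4, 0, 2000), 9000, dt = 0.5,
                               seed = seed),
    "fig4-pulse" = run_config(adapted(alpha, 0.1),
                              stim_step(8, onset = 1000, duration = 1000,
                                        baseline = 1),
                              5000, dt = 0.5, seed = seed),
    "fig5-variance" = run_config(adapted(alpha, 0.1),
                                 stim_noisy(5, 1, tau_filter = 2, seed = seed,
                                            variance_schedule = list(
                                              c(1000, 1), c(1000, 4),
                                              c(1000, 2), c(1000, 1),
                                              c(1000, 2), c(1000, 1),
                                              c(1000, 4), c(1000, 2))),
                                 8000, dt = 0.5, seed = seed),
    "fig6-reliability" = run_config(std(alpha),
                                    stim_noisy(0.52, 0.03, tau_filter = 2,
                                               seed = seed),
                                    10000, dt = 0.5, seed = seed),
    "fig9-compare" = run_config(adapted(alpha, 0.1), stim_step(3), 4000,
                                dt = 0.5, memory_mode = "reset_on_spike",
                                seed = seed),
    stop(sprintf("unknown protocol preset '%s'", name), call. = FALSE))
}

#' Generate self-contained test fixtures
#'
#' Synthesizes the reference curves that stand in for digitized experimental
#' data (all model-generated, at known exponents): (a) ISI-versus-index
#' curves at alpha in {0.15, 0.2, 0.4}, noiseless and with 5% multiplicative
#' noise; (b) rate-versus-time curves under a 16 s square-wave drive; (c)
#' raster ensembles for reliability tests. Each CSV gets a JSON sidecar
#' recording the generating parameters. Identical seeds regenerate
#' identical files.
#'
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param dt time step (ms).
#' @param quiet suppress log lines.
#' @return Character vector of written files, invisibly.
#' @export
generate_fixtures <- function(seed, out_dir, dt = 0.5, quiet = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name, meta) {
    csv <- file.path(out_dir, paste0(name, ".csv"))
    side <- file.path(out_dir, paste0(name, ".json"))
    df[] <- lapply(df, function(col) signif(col, 9))
    write.csv(df, csv, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
    written <<- c(written, csv, side)
  }

  # (a) ISI-vs-index curves
  for (a in c(0.15, 0.2, 0.4)) {
    p <- flif_params(alpha = a, preset = "adapted")
    sim <- flif_simulate(p, rep(4, round(2000 / dt)), dt = dt)
    isi <- diff(sim$spikes)
    meta <- list(kind = "isi_vs_index", alpha = a, amplitude_nA = 4,
                 duration_ms = 2000, dt = dt, preset = "adapted",
                 noise = 0, seed = seed)
    nm <- sprintf("isi_alpha%03d", round(100 * a))
    emit(data.frame(index = seq_along(isi), isi_ms = isi), nm, meta)
    noisy <- isi * (1 + 0.05 * with_seed(seed + round(1000 * a),
                                         rnorm(length(isi))))
    meta$noise <- 0.05
    emit(data.frame(index = seq_along(noisy), isi_ms = noisy),
         paste0(nm, "_noisy"), meta)
  }

  # (b) rate-vs-time under square-wave drive
  p <- flif_params(alpha = 0.2, preset = "adapted")
  n <- round(32000 / dt)
  cur <- render_stimulus(stim_square(3.4, 4, 16000), n, dt)
  sim <- flif_simulate(p, cur, dt = dt)
  r <- instantaneous_rate(sim$spikes)
  emit(data.frame(time_ms = r$time_ms, rate_hz = r$rate_hz),
       "rate_square16s",
       list(kind = "rate_vs_time", alpha = 0.2, low_nA = 3.4, high_nA = 4,
            period_ms = 16000, dt = dt, preset = "adapted", seed = seed))

  # (c) raster ensembles for reliability
  for (a in c(1, 0.2)) {
    p <- flif_params(alpha = a)
    I0 <- calibrate_current(p, target_hz = 14, duration_ms = 2000, dt = dt)
    rows <- do.call(rbind, lapply(1:10, function(tr) {
      cur <- noisy_current(round(2000 / dt), dt, mean = I0, sigma = 0.5,
                           tau_filter = 2, seed = seed + 100L * tr +
                             round(10 * a))
      s <- flif_simulate(p, cur, dt = dt)$spikes
      if (length(s)) data.frame(trial = tr, spike_time_ms = s) else NULL
    }))
    emit(rows, sprintf("raster_alpha%03d", round(100 * a)),
         list(kind = "raster", alpha = a, current_nA = I0, sigma_nA = 0.5,
              tau_filter_ms = 2, n_trials = 10, duration_ms = 2000,
              dt = dt, seed = seed))
  }
  if (!quiet) message(sprintf("INFO fixtures: %d files in %s",
                              length(written), out_dir))
  invisible(written)
}
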