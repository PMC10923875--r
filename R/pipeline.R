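#' Experiment configuration
#'
#' Bundles every setting of an end-to-end experiment: connectome source,
#' stimulated-node scenario, dynamics and hemodynamics parameters, window
#' specification, duration and grids, ensemble size and seeds, and module
#' template. Defaults define a desk-scale study: a 60-node, 4-module
#' synthetic connectome, 6 stimulated nodes, the standard oscillator and
#' hemodynamic parameters, a 256 s run sampled at TR = 2 s (128 volumes,
#' hence 114 sliding windows) and a 50-run ensemble.
#'
#' @param connectome a [connectome()] object, or `NULL` to generate a
#'   synthetic one from `synth`.
#' @param synth list of arguments for [generate_synthetic_connectome()]
#'   (used when `connectome` is `NULL`); `seed` defaults to `base_seed`.
#' @param scenario stimulated-node scenario passed to [select_nodes()].
#' @param custom_targets 1-based indices for `scenario = "custom"`/`"wm"`.
#' @param n_targets number of stimulated nodes (default 6).
#' @param fhn an [fhn_params()].
#' @param stimulus_amplitude,stimulus_period square-wave input amplitude
#'   and period (seconds).
#' @param stimulus_enabled logical; `FALSE` switches the input off.
#' @param balloon a [balloon_params()].
#' @param window a [window_spec()].
#' @param duration,dt,TR simulated span, integration step and repetition
#'   time, all in seconds.
#' @param n_runs ensemble size.
#' @param base_seed seed of the first run (run r uses `base_seed + r - 1`).
#' @param template a [module_template()], or `NULL` to generate a synthetic
#'   one with `template_modules` modules (seeded from `base_seed`).
#' @param template_modules module count of the synthetic template
#'   (default 15).
#' @param out_dir optional directory; when set, [run_experiment()] writes
#'   per-run and mean flexibility CSVs and a JSON manifest there.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(connectome = NULL,
                              synth = list(n_nodes = 60, n_modules = 4),
                              scenario = "mid", custom_targets = NULL,
                              n_targets = 6,
                              fhn = fhn_params(),
                              stimulus_amplitude = 3, stimulus_period = 60,
                              stimulus_enabled = TRUE,
                              balloon = balloon_params(),
                              window = window_spec(),
                              duration = 256, dt = 0.01, TR = 2,
                              n_runs = 50, base_seed = 1,
                              template = NULL, template_modules = 15,
                              out_dir = NULL) {
  if (abs(duration / TR - round(duration / TR)) > 1e-8)
    stop("'duration' must be an integer multiple of TR")
  if (abs(TR / dt - round(TR / dt)) > 1e-8)
    stop("'TR' must be an integer multiple of dt")
  structure(list(connectome = connectome, synth = synth,
                 scenario = scenario, custom_targets = custom_targets,
                 n_targets = n_targets, fhn = fhn,
                 stimulus_amplitude = stimulus_amplitude,
                 stimulus_period = stimulus_period,
                 stimulus_enabled = stimulus_enabled,
                 balloon = balloon, window = window,
                 duration = duration, dt = dt, TR = TR,
                 n_runs = n_runs, base_seed = base_seed,
                 template = template, template_modules = template_modules,
                 out_dir = out_dir),
            class = "experiment_config")
}

resolve_connectome <- function(config) {
  if (!is.null(config$connectome)) return(config$connectome)
  args <- config$synth
  if (is.null(args$seed)) args$seed <- config$base_seed
  do.call(generate_synthetic_connectome, args)
}

resolve_template <- function(config, n_nodes) {
  if (!is.null(config$template)) return(config$template)
  generate_synthetic_template(n_nodes, config$template_modules,
                              seed = config$base_seed)
}

# A window pair (win-1, win) is labeled input-on when the midpoint of the
# later window falls in the I = c half of the stimulus period.
input_phase_annotation <- function(window_mid_times, period) {
  phase <- (window_mid_times %% period) / period
  phase >= 0.5
}

#' Run an end-to-end ensemble experiment
#'
#' Executes, per run: FHN integration with random initial conditions ->
#' Balloon-Windkessel BOLD transform -> sliding-window functional matrices
#' -> template and distance flexibility series; then averages the series
#' window-pair-wise across runs. Flexibility is averaged (not BOLD or the
#' functional matrices), matching how ensemble results are reported.
#'
#' @param config an [experiment_config()].
#' @return An object of class `"ensemble_summary"`: list with `runs`
#'   (per-run list of flexibility series), `mean_template`,
#'   `mean_distance`, `pair_times`, `input_on` (logical annotation per
#'   window pair), `targets` (the node selection used), `seeds` and
#'   `config`. If `config$out_dir` is set, writes `flex_mean.csv`,
#'   `flex_runs/<r>.csv` and `manifest.json` there.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  G <- resolve_connectome(config)
  M <- resolve_template(config, G$n_nodes)
  if (M$n_regions != G$n_nodes)
    stop("template regions must match connectome nodes")
  targets <- select_nodes(G, config$scenario, count = config$n_targets,
                          custom_indices = config$custom_targets)
  protocol <- stimulus_protocol(targets, config$stimulus_amplitude,
                                config$stimulus_period,
                                enabled = config$stimulus_enabled)
  runs <- run_ensemble(G, config$fhn, protocol, config$duration, config$dt,
                       n_runs = config$n_runs, base_seed = config$base_seed,
                       f = function(traj) {
                         Y <- bold_transform(traj, config$balloon, config$TR)
                         fc <- sliding_window_corr(Y, config$window)
                         flexibility_series(fc, M)
                       })
  seeds <- attr(runs, "seeds")
  mean_template <- rowMeans(vapply(runs, `[[`, numeric(length(runs[[1]]$template)),
                                   "template"))
  mean_distance <- rowMeans(vapply(runs, `[[`, numeric(length(runs[[1]]$distance)),
                                   "distance"))
  pair_times <- runs[[1]]$pair_times
  # midpoint of the later window of the pair
  mids <- pair_times + (config$window$length_l - 1) * config$window$delta_t / 2
  summary <- structure(list(runs = runs,
                            mean_template = mean_template,
                            mean_distance = mean_distance,
                            pair_times = pair_times,
                            input_on = input_phase_annotation(mids,
                                                              config$stimulus_period),
                            targets = targets, seeds = seeds,
                            config = config),
                       class = "ensemble_summary")
  if (!is.null(config$out_dir)) write_summary(summary, config$out_dir)
  summary
}

write_summary <- function(summary, out_dir) {
  dir.create(file.path(out_dir, "flex_runs"), recursive = TRUE,
             showWarnings = FALSE)
  np <- length(summary$mean_distance)
  mean_df <- data.frame(win_pair = seq_len(np),
                        template_flexibility = summary$mean_template,
                        distance_flexibility = summary$mean_distance,
                        input_on = summary$input_on)
  write.csv(mean_df, file.path(out_dir, "flex_mean.csv"), row.names = FALSE)
  for (r in seq_along(summary$runs)) {
    run_df <- data.frame(win_pair = seq_len(np),
                         template_flexibility = summary$runs[[r]]$template,
                         distance_flexibility = summary$runs[[r]]$distance)
    write.csv(run_df, file.path(out_dir, "flex_runs", paste0(r, ".csv")),
              row.names = FALSE)
  }
  cfg <- summary$config
  manifest <- list(package_version = as.character(utils::packageVersion("brainflex")),
                   n_nodes = summary$runs[[1]]$n_nodes,
                   scenario = cfg$scenario,
                   targets = summary$targets$indices,
                   fhn = unclass(cfg$fhn), balloon = unclass(cfg$balloon),
                   stimulus = list(amplitude = cfg$stimulus_amplitude,
                                   period = cfg$stimulus_period,
                                   enabled = cfg$stimulus_enabled),
                   window = unclass(cfg$window),
                   duration = cfg$duration, dt = cfg$dt, TR = cfg$TR,
                   n_runs = cfg$n_runs, base_seed = cfg$base_seed,
                   seeds = summary$seeds)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble summary: %d runs, %d window pairs, scenario '%s'\n",
              length(x$runs), length(x$mean_distance), x$config$scenario))
  invisible(x)
}

#' Compare two flexibility series
#'
#' Pearson correlation and mean absolute error between two aligned series
#' (e.g. empirical vs simulated ensemble means, or baseline vs shuffled).
#' The correlation of a constant series is undefined and reported as `NaN`
#' with a warning; the MAE is always returned.
#'
#' @param series_a,series_b numeric vectors of equal length (>= 3).
#' @return List with `pearson_r` and `mae`.
#' @export
compare_flexibility <- function(series_a, series_b) {
  a <- as.numeric(series_a); b <- as.numeric(series_b)
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 3L) stop("series too short to compare")
  r <- if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("constant series: Pearson correlation undefined")
    NaN
  } else cor(a, b)
  list(pearson_r = r, mae = mean(abs(a - b)))
}

#' Run a battery of node-selection and null-model scenarios
#'
#' Repeats the same ensemble experiment under several scenarios sharing all
#' dynamics, hemodynamics and window parameters — and the same run seeds —
#' varying only what the scenario defines: `"baseline"` uses the base
#' configuration's connectome and targets; `"shuffled"` replaces the
#' connectome by its shuffle-null surrogate (one fixed surrogate per
#' battery, derived with `shuffle_seed`); `"wm"` stimulates the
#' `custom_targets`; `"light"`, `"mid"`, `"heavy"` re-select targets by
#' weighted degree.
#'
#' @param base_config an [experiment_config()].
#' @param scenarios character subset of
#'   `c("baseline", "shuffled", "wm", "light", "mid", "heavy")`.
#' @param shuffle_seed seed of the shuffle-null surrogate (default
#'   `base_config$base_seed`).
#' @return A list of class `"scenario_battery"`: `summaries` (named list of
#'   `"ensemble_summary"`) and `comparisons` (data frame of pairwise
#'   Pearson r and MAE between ensemble-mean series).
#' @export
scenario_battery <- function(base_config,
                             scenarios = c("baseline", "shuffled"),
                             shuffle_seed = NULL) {
  stopifnot(inherits(base_config, "experiment_config"))
  known <- c("baseline", "shuffled", "wm", "light", "mid", "heavy")
  if (!all(scenarios %in% known))
    stop("unknown scenario(s): ", paste(setdiff(scenarios, known), collapse = ", "))
  if (is.null(shuffle_seed)) shuffle_seed <- base_config$base_seed
  G <- resolve_connectome(base_config)
  base_config$connectome <- G        # freeze, so all scenarios share it
  base_targets <- select_nodes(G, base_config$scenario,
                               count = base_config$n_targets,
                               custom_indices = base_config$custom_targets)
  summaries <- list()
  for (sc in scenarios) {
    cfg <- base_config
    cfg$out_dir <- NULL
    if (sc == "shuffled") {
      # only the structural matrix changes: same stimulated regions as baseline
      cfg$connectome <- shuffle_connectome(G, seed = shuffle_seed)
      cfg$scenario <- "custom"
      cfg$custom_targets <- base_targets$indices
    } else if (sc != "baseline") {
      cfg$scenario <- sc
      cfg$custom_targets <- NULL
    }
    summaries[[sc]] <- run_experiment(cfg)
  }
  pairs <- if (length(scenarios) > 1) utils::combn(scenarios, 2) else NULL
  comparisons <- NULL
  if (!is.null(pairs)) {
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      ct <- compare_flexibility(summaries[[a]]$mean_template,
                                summaries[[b]]$mean_template)
      cd <- compare_flexibility(summaries[[a]]$mean_distance,
                                summaries[[b]]$mean_distance)
      data.frame(scenario_a = a, scenario_b = b,
                 template_r = ct$pearson_r, template_mae = ct$mae,
                 distance_r = cd$pearson_r, distance_mae = cd$mae)
    }))
  }
  structure(list(summaries = summaries, comparisons = comparisons,
                 shuffle_seed = shuffle_seed),
            class = "scenario_battery")
}

#' Periodicity score of a flexibility series
#'
#' Quantifies how strongly a series oscillates at the task period: the
#' ratio of periodogram power at the frequency closest to
#' `1/input_period_windows` (in window-pair units; the 60 s input with 2 s
#' windows steps gives a period of 30 window pairs) to the median power
#' over all nonzero frequencies. Values far above 1 indicate a regular
#' oscillation locked to the task blocks; a constant series scores 0.
#'
#' @param series numeric vector (a flexibility series) of length
#'   `>= 2 * input_period_windows`.
#' @param input_period_windows task period in window-pair samples
#'   (default 30).
#' @return Nonnegative scalar.
#' @export
periodicity_score <- function(series, input_period_windows = 30) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 2 * input_period_windows)
    stop("series shorter than two input periods")
  x <- x - mean(x)
  if (all(x == 0)) return(0)
  p <- Mod(fft(x))^2 / n
  k <- seq_len(n %/% 2)                  # nonzero frequencies k/n
  target <- k[which.min(abs(k / n - 1 / input_period_windows))]
  p[target + 1L] / median(p[k + 1L])
}
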