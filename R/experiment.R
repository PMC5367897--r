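#' Default experiment configuration
#'
#' A fully serializable description of an end-to-end run: stimulus
#' constants, the condition grid (sizes x localized/non-localized x
#' repetitions; 31 conditions x 30 repetitions = 930 trials by default),
#' model choice with parameters, and analysis settings. A run is
#' reproducible from config + seed alone.
#'
#' @return nested list of class `experiment_config`.
#' @export
default_config <- function() {
  structure(list(
    stimulus = list(f_min = 400, span_oct = 2.2, steps_per_octave = 12,
                    n_bins = 8, max_tones = 26, chord_dur = 0.030,
                    tones_per_octave = 2, levels = c(0.083, 0.125, 0.188),
                    change_time_mean = 3.2, change_time_cap = 8,
                    level_range = c(60, 80), window = 2,
                    sample_rate = 16000),
    conditions = list(sizes = c(50, 80, 110, 140), nonlocalized_size = 110,
                      distances = c(2, 3, 5, 7), n_reps = 30),
    model = list(name = "dual",
                 dual = list(tau_f = 0.2, tau_s = 1.1, tau_a = 1.5,
                             threshold = 0.9, t_motor = 0.25, dt = 0.010),
                 cortical = list(omega = 0.72, Omega = 0.54, a = 5, b = 8,
                                 lam = 1.14, t_motor = 0.25)),
    analysis = list(n_time_bins = 6, dprime_dt = 0.25, fa_dt = 0.25,
                    n_boot = 0)
  ), class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' @param config an [default_config()]-style list.
#' @return the config, invisibly; stops naming the offending key otherwise.
#' @export
validate_config <- function(config) {
  need <- c("stimulus", "conditions", "model", "analysis")
  for (k in need) if (is.null(config[[k]])) stop("config missing key: ", k)
  if (config$conditions$n_reps < 1)
    stop("config key conditions$n_reps must be >= 1")
  if (!config$model$name %in% c("dual", "cortical"))
    stop("config key model$name must be 'dual' or 'cortical'")
  if (config$stimulus$chord_dur <= 0)
    stop("config key stimulus$chord_dur must be positive")
  invisible(config)
}

#' Read / write an experiment configuration as YAML
#'
#' @param config an experiment config.
#' @param path YAML file path.
#' @return `path` (write) or the config (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(utils::modifyList(unclass(default_config()), cfg),
            class = "experiment_config")
}

#' Run a full synthetic experiment
#'
#' Generates the trial batch, simulates the configured model, analyzes the
#' responses, and writes `trials.csv`, `responses.csv`, `psychometrics.csv`,
#' `dprime.csv`, `fa_rate.csv`, `fits.json` and `log.txt` into `out_dir`.
#' Deterministic given config + seed; partial outputs are removed on failure.
#'
#' @param config an experiment config (validated).
#' @param seed top-level seed; per-trial seeds derive from it.
#' @param out_dir output directory (created; must not exist or be empty).
#' @param n_reps optional override of the configured repetitions.
#' @param quiet suppress progress messages.
#' @return list with `trials`, `records`, `psychometrics`, `dprime`,
#'   `fa_rate`, `erlang`, invisibly.
#' @export
run_experiment <- function(config = default_config(), seed = 1,
                           out_dir = NULL, n_reps = NULL, quiet = FALSE) {
  validate_config(config)
  if (!is.null(n_reps)) config$conditions$n_reps <- n_reps
  if (config$conditions$n_reps < 1) stop("config key n_reps must be >= 1")
  created <- FALSE
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)))
      stop("out_dir exists and is not empty: ", out_dir)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    created <- TRUE
    ok <- FALSE
    on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE))
  }
  say <- function(...) if (!quiet) message(...)
  logline <- character(0)

  st <- config$stimulus
  cond <- condition_grid(config$conditions$sizes,
                         config$conditions$nonlocalized_size,
                         config$conditions$distances, st$n_bins)
  trials <- generate_trials(cond, config$conditions$n_reps, seed = seed,
                            change_time_mean = st$change_time_mean,
                            change_time_cap = st$change_time_cap,
                            window = st$window,
                            level_range = st$level_range)
  logline <- c(logline, sprintf("seed=%d n_trials=%d", seed, nrow(trials)))
  say("generated ", nrow(trials), " trials")

  grid <- tone_grid(st$f_min, st$span_oct, st$steps_per_octave, st$n_bins,
                    st$max_tones)
  lambda <- st$tones_per_octave * st$span_oct
  if (config$model$name == "dual") {
    mp <- config$model$dual
    params <- dual_params(mp$tau_f, mp$tau_s, mp$tau_a, mp$threshold,
                          mp$t_motor, mp$dt)
    records <- simulate_dual(trials, params, lambda = lambda, grid = grid,
                             window = st$window, seed = derive_seed(seed, 0))
    logline <- c(logline, sprintf(
      "model=dual tau_f=%g tau_s=%g tau_a=%g T=%g", mp$tau_f, mp$tau_s,
      mp$tau_a, mp$threshold))
  } else {
    mp <- config$model$cortical
    params <- cortical_params(mp$omega, mp$Omega, mp$a, mp$b, mp$lam,
                              mp$t_motor)
    records <- simulate_cortical(trials, params, grid,
                                 sample_rate = st$sample_rate,
                                 window = st$window,
                                 seed = derive_seed(seed, 0))
    logline <- c(logline, sprintf(
      "model=cortical omega=%g Omega=%g a=%g b=%g lam=%g", mp$omega,
      mp$Omega, mp$a, mp$b, mp$lam))
  }
  say("simulated ", config$model$name, " model: ",
      sum(records$outcome == "hit"), " hits, ",
      sum(records$outcome == "false_alarm"), " false alarms")

  an <- config$analysis
  psych <- performance_table(records, an$n_time_bins)
  dp <- time_dependent_dprime(records, window = st$window,
                              dt = an$dprime_dt, n_boot = an$n_boot)
  fa <- instantaneous_fa_rate(records, dt = an$fa_dt)
  erl <- tryCatch(fit_erlang_cdf(psych), error = function(e) NULL)
  if (is.null(erl)) logline <- c(logline, "erlang fit skipped (too few bins)")

  out <- list(trials = trials, records = records, psychometrics = psych,
              dprime = as.data.frame(dp), fa_rate = fa, erlang = erl)
  if (!is.null(out_dir)) {
    write_trials(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(records, file.path(out_dir, "responses.csv"),
                     row.names = FALSE)
    utils::write.csv(psych, file.path(out_dir, "psychometrics.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(dp), file.path(out_dir, "dprime.csv"),
                     row.names = FALSE)
    utils::write.csv(fa, file.path(out_dir, "fa_rate.csv"),
                     row.names = FALSE)
    fits <- list(model = config$model$name,
                 params = config$model[[config$model$name]],
                 erlang = if (!is.null(erl))
                   list(k = erl$k, params = erl$params) else NULL)
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(logline, file.path(out_dir, "log.txt"))
    ok <- TRUE
  }
  invisible(out)
}
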