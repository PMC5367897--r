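#' Standard condition grid for a change-detection session
#'
#' The standard design crosses localized changes (4 adjacent bin pairs x the
#' requested change sizes) with non-localized changes (all pairs at bin
#' distances 2, 3, 5, 7, at 110% only): 16 + 15 = 31 conditions, 930 trials
#' at 30 repetitions each.
#'
#' @param sizes localized change sizes in percent.
#' @param nonlocalized_size change size for the non-localized conditions
#'   (`NULL` drops them).
#' @param distances non-localized bin distances.
#' @param n_bins number of spectral bins.
#' @return data.frame with columns `change_size`, `bin_lo`, `bin_hi`,
#'   `distance`, `localized`.
#' @export
condition_grid <- function(sizes = c(50, 80, 110, 140),
                           nonlocalized_size = 110,
                           distances = c(2, 3, 5, 7), n_bins = 8) {
  loc <- change_bin_pairs(n_bins, 1)
  out <- do.call(rbind, lapply(sizes, function(s)
    data.frame(change_size = s, bin_lo = loc[, 1], bin_hi = loc[, 2],
               distance = 1L, localized = TRUE)))
  if (!is.null(nonlocalized_size)) {
    for (d in distances) {
      pr <- change_bin_pairs(n_bins, d)
      out <- rbind(out, data.frame(change_size = nonlocalized_size,
                                   bin_lo = pr[, 1], bin_hi = pr[, 2],
                                   distance = as.integer(d),
                                   localized = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# deterministic counter-based per-trial seed derivation (all < 2^31)
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 + 1664525 * index) %% 2147483647)
}

#' Generate a batch of trial specifications
#'
#' Each trial gets a pseudo-randomly permuted baseline marginal, an
#' exponentially distributed change time (mean 3.2 s, capped at 8 s), a roved
#' presentation level in 60-80 dB and a per-trial seed derived from the batch
#' seed by a counter scheme, so any trial can be re-realized in isolation.
#' The trial lasts until 2 s after the change (the response window).
#'
#' @param conditions a [condition_grid()]-style data.frame.
#' @param n_reps repetitions of each condition.
#' @param seed batch seed.
#' @param change_time_mean,change_time_cap truncated-exponential parameters
#'   in seconds.
#' @param window response window after the change, seconds.
#' @param level_range level roving range in dB.
#' @return data.frame, one row per trial: `trial`, condition columns,
#'   `change_time`, `max_duration`, `level_db`, `level_perm` (baseline level
#'   assignment, e.g. "31132123"), `seed`.
#' @export
generate_trials <- function(conditions = condition_grid(), n_reps = 30,
                            seed = 1, change_time_mean = 3.2,
                            change_time_cap = 8, window = 2,
                            level_range = c(60, 80)) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  trials <- conditions[rep(seq_len(nrow(conditions)), each = n_reps), ,
                       drop = FALSE]
  n <- nrow(trials)
  set.seed(seed)
  trials$trial <- seq_len(n)
  trials$change_time <- sample_change_time(n, change_time_mean,
                                           change_time_cap)
  trials$max_duration <- trials$change_time + window
  trials$level_db <- stats::runif(n, level_range[1], level_range[2])
  trials$level_perm <- vapply(seq_len(n), function(i)
    paste(sample(rep.int(1:3, .marginal_counts)), collapse = ""),
    character(1))
  trials$seed <- derive_seed(seed, seq_len(n))
  rownames(trials) <- NULL
  trials[, c("trial", "change_size", "bin_lo", "bin_hi", "distance",
             "localized", "change_time", "max_duration", "level_db",
             "level_perm", "seed")]
}

#' Baseline and post-change marginals of a trial
#'
#' @param trial one row of a [generate_trials()] table.
#' @return list with `pre` and `post` probability vectors.
#' @export
trial_marginals <- function(trial) {
  idx <- as.integer(strsplit(trial$level_perm, "")[[1]])
  pre <- marginal_from_levels(idx)
  post <- apply_change(pre, c(trial$bin_lo, trial$bin_hi), trial$change_size)
  list(pre = as.numeric(pre), post = post)
}

#' Realize a trial as a chord sequence
#'
#' Reconstructs the stimulus of one trial from its specification row using
#' the trial's own seed, so realizations are reproducible per trial.
#'
#' @param trial one row of a [generate_trials()] table.
#' @param grid a [tone_grid()].
#' @param tones_per_octave mean Poisson tone rate per octave per chord.
#' @return a [generate_chords()] chord sequence.
#' @export
realize_trial <- function(trial, grid = tone_grid(), tones_per_octave = 2) {
  m <- trial_marginals(trial)
  set.seed(trial$seed)
  generate_chords(grid, m$pre, m$post, change_time = trial$change_time,
                  duration = trial$max_duration,
                  tones_per_octave = tones_per_octave)
}

#' Write / read a trial table as CSV
#'
#' UTF-8, header row, '.' decimal, no row names; numeric columns carry full
#' precision so a round trip reproduces identical model inputs.
#'
#' @param trials a [generate_trials()] table.
#' @param path CSV file path.
#' @return `path` (write) or the trial table (read).
#' @export
write_trials <- function(trials, path) {
  out <- trials
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- format(out[[nm]], digits = 17, trim = TRUE,
                          scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(level_perm = "character"))
  tr$localized <- as.logical(tr$localized)
  tr
}
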