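# shared fixtures: everything is generated in code at test time

std_grid <- tone_grid()

# a small localized-change trial batch
small_trials <- function(sizes = c(50, 140), n_reps = 5, seed = 42) {
  generate_trials(condition_grid(sizes = sizes, nonlocalized_size = NULL),
                  n_reps = n_reps, seed = seed)
}

# surrogate random responder: presses with probability p per bin of width dt,
# from stimulus onset until the trial ends (change time + window)
random_responder <- function(change_times, p = 0.01, dt = 0.025,
                             window = 2) {
  vapply(change_times, function(ct) {
    k <- which(stats::rbinom(ceiling((ct + window) / dt), 1L, p) == 1L)[1]
    if (is.na(k)) NA_real_ else k * dt
  }, numeric(1))
}
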