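#' Generate a chord sequence (tone-cloud texture)
#'
#' The texture is a train of 30 ms chords. Each chord contains a Poisson
#' number of tones (mean `tones_per_octave * span_oct`, i.e. 4.4 tones/chord
#' ~ 147 tones/s on the standard grid); each tone picks a spectral bin from
#' the marginal, then a tone frequency uniformly within the bin. Chords are
#' mutually independent; chords starting at or after `change_time` are drawn
#' from the post-change marginal.
#'
#' @param grid a [tone_grid()].
#' @param p_pre baseline marginal over bins.
#' @param p_post post-change marginal (default: no change).
#' @param change_time change onset in seconds from stimulus onset.
#' @param duration total stimulus duration in seconds (>= change_time).
#' @param tones_per_octave mean Poisson tone rate per octave per chord.
#' @param chord_dur chord duration in seconds.
#' @return An object of class `chord_sequence`: list with `chords` (list of
#'   integer tone-index vectors), `chord_dur`, `n_chords`, `change_time`,
#'   `change_chord` (first chord index drawn from `p_post`, or NA),
#'   and `grid`.
#' @export
generate_chords <- function(grid, p_pre, p_post = p_pre, change_time = Inf,
                            duration, tones_per_octave = 2,
                            chord_dur = 0.030) {
  stopifnot(inherits(grid, "tone_grid"))
  if (duration <= 0) stop("duration must be positive")
  if (is.finite(change_time) && duration < change_time)
    stop("duration must be >= change_time")
  check_marginal(p_pre, grid$n_bins)
  check_marginal(p_post, grid$n_bins)

  n_chords <- as.integer(ceiling(duration / chord_dur - 1e-9))
  lambda <- tones_per_octave * grid$span_oct
  counts <- stats::rpois(n_chords, lambda)
  onset <- (seq_len(n_chords) - 1) * chord_dur
  post <- is.finite(change_time) & onset >= change_time - 1e-12

  draw_tones <- function(total, p) {
    if (total == 0L) return(integer(0))
    bins <- sample.int(grid$n_bins, total, replace = TRUE, prob = p)
    # uniform tone within each sampled bin
    offs <- floor(stats::runif(total) * grid$bin_sizes[bins]) + 1L
    first_tone <- c(0L, cumsum(grid$bin_sizes))[bins]
    as.integer(first_tone + offs)
  }
  tones_pre <- draw_tones(sum(counts[!post]), p_pre)
  tones_post <- draw_tones(sum(counts[post]), p_post)

  chords <- vector("list", n_chords)
  i_pre <- 0L; i_post <- 0L
  for (c in seq_len(n_chords)) {
    k <- counts[c]
    if (post[c]) {
      chords[[c]] <- tones_post[seq_len(k) + i_post]; i_post <- i_post + k
    } else {
      chords[[c]] <- tones_pre[seq_len(k) + i_pre]; i_pre <- i_pre + k
    }
  }

  structure(list(
    chords = chords,
    chord_dur = chord_dur,
    n_chords = n_chords,
    change_time = change_time,
    change_chord = if (any(post)) which(post)[1] else NA_integer_,
    grid = grid
  ), class = "chord_sequence")
}

check_marginal <- function(p, n_bins) {
  if (length(p) != n_bins || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("marginal must be a normalized probability vector over ", n_bins,
         " bins")
  invisible(TRUE)
}

#' @export
print.chord_sequence <- function(x, ...) {
  cat("chord_sequence:", x$n_chords, "chords x", format(x$chord_dur * 1000),
      "ms,", sum(lengths(x$chords)), "tones",
      if (is.finite(x$change_time))
        paste0("(change at ", format(x$change_time), " s)") else
        "(no change)", "\n")
  invisible(x)
}

#' Mean tone rate of a chord sequence
#'
#' @param seq a [generate_chords()] result.
#' @return tones per second.
#' @export
tone_rate <- function(seq) {
  stopifnot(inherits(seq, "chord_sequence"))
  sum(lengths(seq$chords)) / (seq$n_chords * seq$chord_dur)
}

#' Binary per-channel event series from a chord sequence
#'
#' Each detector channel watches a pair of spectral bins; its series S_i(t)
#' is 1 throughout any chord containing at least one tone in either bin of
#' the pair, sampled at `1/dt` (the chord duration must be a multiple of
#' `dt`, default 10 ms so each 30 ms chord spans 3 samples).
#'
#' @param seq a [generate_chords()] result.
#' @param pairs two-column matrix of bin pairs (default the localized pair
#'   set from [change_bin_pairs()]).
#' @param dt sampling step in seconds.
#' @param counts return the tone count in the pair per chord instead of the
#'   binary presence indicator (the count is what the dual-timescale
#'   estimators track by default; see [simulate_dual()]).
#' @return numeric matrix, time steps x channels, entries in \{0, 1\} (or
#'   counts); attribute `dt` holds the step.
#' @export
bin_event_series <- function(seq, pairs = change_bin_pairs(seq$grid$n_bins),
                             dt = 0.010, counts = FALSE) {
  stopifnot(inherits(seq, "chord_sequence"))
  k <- seq$chord_dur / dt
  if (abs(k - round(k)) > 1e-8) stop("dt must divide the chord duration")
  k <- as.integer(round(k))
  n_pairs <- nrow(pairs)
  bin_of <- seq$grid$bin_of_tone
  per_chord <- matrix(0, seq$n_chords, n_pairs)
  for (c in seq_len(seq$n_chords)) {
    b <- bin_of[seq$chords[[c]]]
    if (length(b))
      for (i in seq_len(n_pairs)) {
        m <- sum(b == pairs[i, 1] | b == pairs[i, 2])
        per_chord[c, i] <- if (counts) m else as.numeric(m > 0)
      }
  }
  S <- per_chord[rep(seq_len(seq$n_chords), each = k), , drop = FALSE]
  attr(S, "dt") <- dt
  S
}

#' Sample per-channel event series directly by Poisson thinning
#'
#' The distribution of the pair series induced by the chord generator has a
#' closed form: tones per chord are Poisson(lambda) and bins are selected
#' independently from the marginal, so the tone count in a bin pair is
#' Poisson(lambda * p_pair) -- independent across chords and across pairs by
#' Poisson thinning -- and the chord-level presence indicator is
#' Bernoulli(1 - exp(-lambda * p_pair)). Sampling that law directly is
#' exactly equivalent in distribution to [generate_chords()] +
#' [bin_event_series()] and much faster for large trial batches.
#'
#' @param p_pre,p_post marginals over bins before/after the change.
#' @param change_time change onset in seconds.
#' @param duration stimulus duration in seconds.
#' @param lambda mean tones per chord (default 4.4 = 2/octave x 2.2 octaves).
#' @param pairs two-column matrix of bin pairs.
#' @param dt sampling step (must divide `chord_dur`).
#' @param chord_dur chord duration in seconds.
#' @param counts return Poisson tone counts instead of binary presence.
#' @return as [bin_event_series()].
#' @export
sample_event_series <- function(p_pre, p_post = p_pre, change_time = Inf,
                                duration, lambda = 4.4,
                                pairs = change_bin_pairs(length(p_pre)),
                                dt = 0.010, chord_dur = 0.030,
                                counts = FALSE) {
  k <- chord_dur / dt
  if (abs(k - round(k)) > 1e-8) stop("dt must divide the chord duration")
  k <- as.integer(round(k))
  n_chords <- as.integer(ceiling(duration / chord_dur - 1e-9))
  onset <- (seq_len(n_chords) - 1) * chord_dur
  post <- is.finite(change_time) & onset >= change_time - 1e-12
  pp_pre <- p_pre[pairs[, 1]] + p_pre[pairs[, 2]]
  pp_post <- p_post[pairs[, 1]] + p_post[pairs[, 2]]
  per_chord <- matrix(0, n_chords, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    lam <- lambda * ifelse(post, pp_post[i], pp_pre[i])
    per_chord[, i] <- if (counts) stats::rpois(n_chords, lam)
                      else stats::rbinom(n_chords, 1L, 1 - exp(-lam))
  }
  S <- per_chord[rep(seq_len(n_chords), each = k), , drop = FALSE]
  attr(S, "dt") <- dt
  S
}
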