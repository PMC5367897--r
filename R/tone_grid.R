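#' Logarithmic tone-frequency grid partitioned into spectral bins
#'
#' Builds the fixed set of pure-tone frequencies from which tone-cloud
#' textures are assembled: semitone-spaced tones covering `span_oct` octaves
#' above `f_min`, grouped into `n_bins` contiguous spectral bins of 3-4 tones
#' each. The marginal distribution of the texture is defined over these bins,
#' so the bin is the unit at which stimulus statistics are manipulated.
#'
#' With the defaults (400 Hz, 2.2 octaves, 12 semitones/octave) the span
#' admits 27 semitone-spaced tones; `max_tones = 26` drops the topmost so the
#' standard grid holds 26 tones in bins of sizes 4/3/3/3/4/3/3/3. Set
#' `max_tones = Inf` to keep every tone on the span.
#'
#' @param f_min lowest tone frequency in Hz.
#' @param span_oct frequency range in octaves.
#' @param steps_per_octave tone spacing (semitone resolution), tones per octave.
#' @param n_bins number of contiguous spectral bins.
#' @param max_tones cap on the number of tones (topmost tones dropped).
#' @return An object of class `tone_grid`: list with `tone_freqs` (Hz,
#'   increasing), `bin_of_tone` (bin index per tone), `bin_sizes`,
#'   `bin_centers_hz`, `bin_width_st` (bin-center spacing in semitones),
#'   `n_bins`, `f_min`, `span_oct`, `steps_per_octave`.
#' @examples
#' g <- tone_grid()
#' length(g$tone_freqs)  # 26
#' g$bin_width_st        # 3.3 semitones between bin centers
#' @export
tone_grid <- function(f_min = 400, span_oct = 2.2, steps_per_octave = 12,
                      n_bins = 8, max_tones = 26L) {
  if (!is.finite(f_min) || f_min <= 0) stop("f_min must be positive")
  if (!is.finite(span_oct) || span_oct <= 0) stop("span_oct must be positive")
  if (steps_per_octave < 1) stop("steps_per_octave must be >= 1")
  if (n_bins < 1) stop("n_bins must be >= 1")

  k_max <- floor(span_oct * steps_per_octave + 1e-9)
  freqs <- f_min * 2^((0:k_max) / steps_per_octave)
  if (is.finite(max_tones) && length(freqs) > max_tones)
    freqs <- freqs[seq_len(max_tones)]
  n_tones <- length(freqs)
  if (n_tones < n_bins)
    stop("grid has fewer tones (", n_tones, ") than bins (", n_bins, ")")

  # contiguous partition: tone k (0-based) -> bin floor(k * n_bins / n_tones);
  # for 26 tones / 8 bins this yields the 4/3/3/3/4/3/3/3 pattern
  bin_of_tone <- floor((seq_len(n_tones) - 1) * n_bins / n_tones) + 1L
  bin_sizes <- tabulate(bin_of_tone, nbins = n_bins)
  if (any(bin_sizes < 1)) stop("n_bins too large: empty spectral bin")

  bin_width_oct <- span_oct / n_bins
  centers <- f_min * 2^((seq_len(n_bins) - 0.5) * bin_width_oct)

  structure(list(
    tone_freqs = freqs,
    bin_of_tone = bin_of_tone,
    bin_sizes = bin_sizes,
    bin_centers_hz = centers,
    bin_width_st = bin_width_oct * 12,
    n_bins = as.integer(n_bins),
    f_min = f_min,
    span_oct = span_oct,
    steps_per_octave = steps_per_octave
  ), class = "tone_grid")
}

#' @export
print.tone_grid <- function(x, ...) {
  cat("tone_grid:", length(x$tone_freqs), "tones,",
      format(x$f_min), "-", format(round(max(x$tone_freqs), 1)), "Hz,",
      x$n_bins, "bins of", paste(range(x$bin_sizes), collapse = "-"),
      "tones\n")
  invisible(x)
}

#' Distance in semitones between two spectral bins
#'
#' Bin centers are equally spaced on the log-frequency axis, so a separation
#' of `d` bins corresponds to `d * bin_width_st` semitones (3.3 st per bin on
#' the standard grid: distances 2, 3, 5, 7 bins are 6.6, 9.9, 16.5, 23.1 st).
#'
#' @param grid a [tone_grid()].
#' @param d integer bin separation(s).
#' @return numeric vector of distances in semitones.
#' @export
bin_distance_st <- function(grid, d) {
  stopifnot(inherits(grid, "tone_grid"))
  d * grid$bin_width_st
}

#' Enumerate changed-bin pairs
#'
#' Localized changes increment two adjacent bins from the fixed pair set
#' \{1,2\}, \{3,4\}, \{5,6\}, \{7,8\}; non-localized changes increment two
#' bins separated by `distance` bins (all such pairs, e.g. 6 pairs at
#' distance 2 on an 8-bin grid).
#'
#' @param n_bins number of spectral bins.
#' @param distance bin separation; 1 selects the fixed localized pair set.
#' @return two-column integer matrix, one pair per row.
#' @export
change_bin_pairs <- function(n_bins = 8, distance = 1) {
  if (distance == 1) {
    lo <- seq(1L, n_bins - 1L, by = 2L)
    return(cbind(lo = lo, hi = lo + 1L))
  }
  if (distance < 1 || distance > n_bins - 1) stop("invalid bin distance")
  lo <- seq_len(n_bins - distance)
  cbind(lo = lo, hi = lo + as.integer(distance))
}

#' Per-tone draw probability implied by a bin marginal
#'
#' A tone is drawn by first selecting a bin according to the marginal, then a
#' tone uniformly within the bin, so each tone frequency is drawn with
#' probability `p[bin] / bin_size`. On the standard grid with the printed
#' level set \{0.083, 0.125, 0.188\} the extremes are 0.083/4 = 0.021 and
#' 0.188/3 = 0.063 (printed precision); the renormalized marginal gives
#' slightly smaller values.
#'
#' @param p marginal probability vector over bins.
#' @param grid a [tone_grid()].
#' @return numeric vector, one draw probability per tone.
#' @export
tone_draw_probabilities <- function(p, grid) {
  stopifnot(inherits(grid, "tone_grid"), length(p) == grid$n_bins)
  p[grid$bin_of_tone] / grid$bin_sizes[grid$bin_of_tone]
}
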