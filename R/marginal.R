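#' Marginal levels used to build baseline distributions
#'
#' The baseline marginal over 8 bins is a random permutation of a fixed level
#' multiset: three bins at the low level, two at the mid level, three at the
#' high level. The printed levels \{0.083, 0.125, 0.188\} sum to 1.0625; they
#' are treated as rounded and the assigned vector is renormalized to sum to 1.
#'
#' @keywords internal
.marginal_levels <- c(low = 0.083, mid = 0.125, high = 0.188)
.marginal_counts <- c(low = 3L, mid = 2L, high = 3L)

#' Build a marginal distribution from a level assignment
#'
#' @param level_idx integer vector over bins with values in 1..3 indexing the
#'   (low, mid, high) levels; must contain exactly 3 lows, 2 mids, 3 highs.
#' @param levels the discrete level values.
#' @param normalize renormalize to sum exactly to 1 (default).
#' @return numeric probability vector with attributes `level_idx` and `levels`.
#' @export
marginal_from_levels <- function(level_idx, levels = .marginal_levels,
                                 normalize = TRUE) {
  level_idx <- as.integer(level_idx)
  if (!identical(tabulate(level_idx, nbins = 3L), unname(.marginal_counts)))
    stop("level assignment must contain exactly {3 low, 2 mid, 3 high}")
  p <- unname(levels[level_idx])
  if (normalize) p <- p / sum(p)
  structure(p, level_idx = level_idx, levels = levels)
}

#' Sample a baseline marginal distribution
#'
#' Draws a uniformly random permutation of the fixed level multiset
#' \{3 x low, 2 x mid, 3 x high\} over the 8 bins and renormalizes. Uses the
#' session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param n_bins number of bins (must be 8, the composition is fixed).
#' @inheritParams marginal_from_levels
#' @return normalized probability vector of length `n_bins`.
#' @export
sample_marginal <- function(n_bins = 8, levels = .marginal_levels,
                            normalize = TRUE) {
  if (n_bins != 8) stop("the fixed level composition requires 8 bins")
  idx <- sample(rep.int(1:3, .marginal_counts))
  marginal_from_levels(idx, levels = levels, normalize = normalize)
}

#' Apply a change in the marginal distribution
#'
#' Increments two target bins each by `size_pct/100 * (1/n_bins)` (the change
#' size is expressed relative to the uniform single-bin probability, 0.125
#' for 8 bins, so a 50% change adds 0.0625 per bin) and renormalizes, which
#' keeps the expected tone rate constant across the change.
#'
#' @param p baseline marginal probability vector.
#' @param bins integer pair of distinct bin indices to increment.
#' @param size_pct change size in percent of the uniform bin probability
#'   (30, 50, 80, 110 or 140 in the standard design; any non-negative value
#'   is accepted).
#' @return renormalized post-change probability vector.
#' @export
apply_change <- function(p, bins, size_pct) {
  n <- length(p)
  bins <- as.integer(bins)
  if (length(bins) != 2 || anyNA(bins) || any(bins < 1 | bins > n))
    stop("bins must be two valid bin indices")
  if (bins[1] == bins[2]) stop("changed bins must be distinct")
  if (size_pct < 0) stop("size_pct must be non-negative")
  q <- as.numeric(p)
  q[bins] <- q[bins] + size_pct / 100 / n
  q / sum(q)
}

#' Sample change times from a truncated exponential law
#'
#' Change times are exponential with the given mean, restricted to
#' `[0, cap]` by redrawing (rejection), which preserves the flat hazard on
#' the interval; clipping would pile mass at the cap.
#'
#' @param n number of draws.
#' @param mean mean of the untruncated exponential, seconds.
#' @param cap upper limit in seconds (Inf for no truncation).
#' @return numeric vector of change times in seconds.
#' @export
sample_change_time <- function(n = 1, mean = 3.2, cap = 8) {
  stopifnot(mean > 0, cap > 0)
  out <- stats::rexp(n, rate = 1 / mean)
  while (any(bad <- out > cap))
    out[bad] <- stats::rexp(sum(bad), rate = 1 / mean)
  out
}
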