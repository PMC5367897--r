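test_that("tone grid is semitone-spaced, partitioned into 3-4 tone bins", {
  g <- std_grid
  # brute-force enumeration of semitone frequencies on the span
  ks <- 0:100
  f <- 400 * 2^(ks / 12)
  expect_equal(length(f[f <= 400 * 2^2.2 + 1e-9]), 27)  # inclusive count
  expect_equal(length(g$tone_freqs), 26)                # top tone dropped
  expect_equal(g$tone_freqs, 400 * 2^((0:25) / 12))
  expect_true(all(diff(log2(g$tone_freqs)) - 1 / 12 < 1e-12))
  expect_equal(unname(g$bin_sizes), c(4, 3, 3, 3, 4, 3, 3, 3))
  expect_true(all(g$bin_sizes >= 3 & g$bin_sizes <= 4))
  # each tone in exactly one bin, bins contiguous
  expect_equal(length(g$bin_of_tone), 26)
  expect_true(all(diff(g$bin_of_tone) %in% c(0L, 1L)))
  # bin-center spacing 3.3 st; distances 2,3,5,7 bins -> printed table
  expect_equal(g$bin_width_st, 3.3)
  expect_equal(bin_distance_st(g, c(2, 3, 5, 7)), c(6.6, 9.9, 16.5, 23.1))
  # full-span option keeps all 27
  expect_equal(length(tone_grid(max_tones = Inf)$tone_freqs), 27)
  # degenerate single bin holds every tone
  g1 <- tone_grid(n_bins = 1)
  expect_true(all(g1$bin_of_tone == 1L))
  expect_error(tone_grid(span_oct = -1))
  expect_error(tone_grid(n_bins = 40))
})

test_that("baseline marginal is a renormalized {3 low, 2 mid, 3 high} draw", {
  set.seed(1)
  for (i in 1:20) {
    p <- sample_marginal()
    expect_equal(sum(p), 1, tolerance = 1e-12)
    idx <- attr(p, "level_idx")
    expect_equal(unname(tabulate(idx, 3)), c(3L, 2L, 3L))
  }
  expect_error(marginal_from_levels(c(1, 1, 1, 1, 2, 2, 3, 3)))
  # uniform-permutation law: each bin receives the low level with
  # probability 3/8 (chi-square against the enumeration expectation)
  set.seed(2)
  n <- 4000
  lows <- matrix(0, n, 8)
  for (i in seq_len(n))
    lows[i, ] <- attr(sample_marginal(), "level_idx") == 1
  counts <- colSums(lows)
  chi2 <- sum((counts - n * 3 / 8)^2 / (n * 3 / 8 * (1 - 3 / 8)))
  expect_lt(chi2, qchisq(0.999, df = 8))
})

test_that("apply_change increments by size/100 * 1/8 then renormalizes", {
  p <- rep(1 / 8, 8)
  # 50% of the uniform bin probability is 0.0625 before renormalization
  expect_equal(0.5 * 1 / 8, 0.0625)
  q <- apply_change(p, c(1, 2), 0)
  expect_equal(q, p)
  # hand-computed oracle for 110%, uniform base
  inc <- 1.10 / 8
  manual <- p; manual[1:2] <- manual[1:2] + inc; manual <- manual / sum(manual)
  expect_equal(apply_change(p, c(1, 2), 110), manual)
  expect_equal(sum(manual), 1, tolerance = 1e-12)
  # changed bins strictly up, others strictly down, for every size
  set.seed(3)
  for (s in c(30, 50, 80, 110, 140)) {
    p <- sample_marginal()
    q <- apply_change(p, c(3, 4), s)
    expect_true(all(q[3:4] > p[3:4]))
    expect_true(all(q[-(3:4)] < p[-(3:4)]))
    expect_equal(sum(q), 1, tolerance = 1e-12)
  }
  expect_error(apply_change(p, c(1, 1), 50))
  expect_error(apply_change(p, c(0, 2), 50))
})

test_that("change times are truncated-exponential with flat hazard", {
  set.seed(4)
  x <- sample_change_time(2e5, mean = 3.2, cap = 8)
  expect_true(all(x >= 0 & x <= 8))
  # analytic mean of the conditioned law E[X | X <= 8]
  m <- 3.2; cap <- 8
  cond_mean <- m - cap * exp(-cap / m) / (1 - exp(-cap / m))
  expect_equal(mean(x), cond_mean, tolerance = 0.02)
  # untruncated mean recovers 3.2
  y <- sample_change_time(2e5, mean = 3.2, cap = Inf)
  expect_equal(mean(y), 3.2, tolerance = 0.02)
  # untruncated draws have a flat empirical hazard on [0.5, 6]
  br <- seq(0, 8, by = 0.25)
  haz <- function(v) vapply(seq_len(length(br) - 1), function(i)
    sum(v >= br[i] & v < br[i + 1]) / sum(v >= br[i]), numeric(1))
  sel <- br[-length(br)] >= 0.5 & br[-length(br)] <= 6
  hy <- haz(y)[sel]
  expect_lt(max(hy) / min(hy), 1.15)
  # truncation by redraw keeps the exponential density shape on [0, 8]:
  # the empirical hazard matches the truncated law's analytic hazard
  hx <- haz(x)[sel]
  t_mid <- br[-length(br)][sel] + 0.125
  h_true <- 1 - exp(-0.25 / m) * (1 - exp(-(cap - t_mid - 0.25) / m)) /
    (1 - exp(-(cap - t_mid) / m))
  expect_lt(max(abs(hx / h_true - 1)), 0.1)
})

test_that("chord generator matches Poisson tone statistics", {
  set.seed(5)
  p <- sample_marginal()
  s <- generate_chords(std_grid, p, duration = 100)
  expect_equal(s$n_chords, ceiling(100 / 0.03))
  # ~147 tones/s = 2 tones/oct * 2.2 oct / 30 ms
  expect_equal(tone_rate(s), 4.4 / 0.03, tolerance = 0.02)
  # marginal concentrated on one bin -> all tones in that bin
  p1 <- c(0, 0, 1, 0, 0, 0, 0, 0)
  s1 <- generate_chords(std_grid, p1, duration = 5)
  tones <- unlist(s1$chords)
  expect_true(all(std_grid$bin_of_tone[tones] == 3L))
  # expected tones per chord identical before and after a change
  q <- apply_change(p, c(1, 2), 140)
  s2 <- generate_chords(std_grid, p, q, change_time = 20, duration = 40)
  n_pre <- sum(lengths(s2$chords[1:666]))
  n_post <- sum(lengths(s2$chords[668:1334]))
  expect_equal(n_pre / n_post, 1, tolerance = 0.1)
  expect_error(generate_chords(std_grid, p, duration = -1))
})

test_that("per-tone draw probabilities span the printed extremes", {
  # printed level set over bin sizes 4 and 3: 0.083/4 and 0.188/3
  p_raw <- marginal_from_levels(c(1, 2, 1, 3, 3, 2, 1, 3), normalize = FALSE)
  dp <- tone_draw_probabilities(p_raw, std_grid)
  expect_equal(min(dp), 0.021, tolerance = 0.02)
  expect_equal(max(dp), 0.063, tolerance = 0.02)
  # and they are p_bin / bin size exactly
  expect_equal(dp[1], 0.083 / 4)
})

test_that("event series mark chords with tones in the watched pair", {
  g <- std_grid
  # single chord with one tone in bin 3 -> channel {3,4} on, others off
  s <- generate_chords(g, c(0, 0, 1, 0, 0, 0, 0, 0), duration = 0.03)
  S <- bin_event_series(s)
  expect_equal(dim(S), c(3L, 4L))
  expect_true(all(S[, 2] == 1))
  expect_true(all(S[, -2] == 0))
  # empty chords -> all-zero series
  p <- rep(1 / 8, 8)
  s2 <- generate_chords(g, p, duration = 1, tones_per_octave = 0)
  expect_true(all(bin_event_series(s2) == 0))
  # Poisson-thinning closed form: mean of S_i = 1 - exp(-lambda p_pair)
  set.seed(6)
  p <- sample_marginal()
  s3 <- generate_chords(g, p, duration = 120)
  S3 <- bin_event_series(s3)
  pairs <- change_bin_pairs(8)
  for (i in 1:4) {
    expe <- 1 - exp(-4.4 * sum(p[pairs[i, ]]))
    expect_equal(mean(S3[, i]), expe, tolerance = 0.03)
  }
  # thinning sampler agrees with the symbolic path in distribution
  S4 <- sample_event_series(p, duration = 120)
  expect_equal(colMeans(S4), colMeans(S3), tolerance = 0.03)
  # count mode matches Poisson pair means
  S5 <- sample_event_series(p, duration = 120, counts = TRUE)
  expect_equal(colMeans(S5), 4.4 * (p[pairs[, 1]] + p[pairs[, 2]]),
               tolerance = 0.05)
})

test_that("rendered waveform matches the symbolic stimulus", {
  g <- std_grid
  # empty chords -> silence of correct length
  s0 <- generate_chords(g, rep(1 / 8, 8), duration = 0.3,
                        tones_per_octave = 0)
  w0 <- render_waveform(s0, 70, 16000)
  expect_equal(length(w0), 10 * 480)
  expect_true(all(w0 == 0))
  # single 400 Hz tone -> FFT argmax at 400 Hz
  s1 <- structure(list(chords = list(1L), chord_dur = 0.03, n_chords = 1L,
                       change_time = Inf, change_chord = NA_integer_,
                       grid = g), class = "chord_sequence")
  w1 <- render_waveform(s1, 70, 16000)
  sp <- Mod(fft(c(w1, numeric(16000 - length(w1)))))[1:8000]
  expect_equal(which.max(sp) - 1, 400, tolerance = 0.01)
  # +6.02 dB when level rises by 6.02 dB
  w2 <- render_waveform(s1, 76.02, 16000)
  expect_equal(sqrt(mean(w2^2)) / sqrt(mean(w1^2)), 2, tolerance = 1e-3)
  expect_error(render_waveform(s1, 70, sample_rate = 3000))
  # WAV round trip
  f <- tempfile(fileext = ".wav")
  write_wav(w1, f)
  w1b <- read_wav(f)
  expect_equal(attr(w1b, "sample_rate"), 16000)
  expect_equal(as.numeric(w1b), as.numeric(w1), tolerance = 1e-6)
  unlink(f)
})

test_that("trial batches are reproducible and round-trip through CSV", {
  tr1 <- small_trials()
  tr2 <- small_trials()
  expect_identical(tr1, tr2)
  expect_true(all(tr1$change_time <= 8))
  expect_true(all(tr1$level_db >= 60 & tr1$level_db <= 80))
  expect_true(all(tr1$max_duration == tr1$change_time + 2))
  f <- tempfile(fileext = ".csv")
  write_trials(tr1, f)
  tr3 <- read_trials(f)
  expect_equal(tr3$change_time, tr1$change_time, tolerance = 1e-15)
  expect_identical(tr3$level_perm, tr1$level_perm)
  # identical realization from the stored per-trial seed
  s_a <- realize_trial(tr1[3, ], std_grid)
  s_b <- realize_trial(tr3[3, ], std_grid)
  expect_identical(s_a$chords, s_b$chords)
  unlink(f)
  # standard design: 31 conditions (16 localized + 15 non-localized pairs)
  cond <- condition_grid()
  expect_equal(nrow(cond), 31)
  expect_equal(sum(!cond$localized & cond$distance == 2), 6)
})
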