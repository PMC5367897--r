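# spectral kernel width convention: FWHM (octaves) * scale (cyc/oct) is held
# at 0.3024 cycles, so the 0.54 cyc/oct filter has a 0.56-octave FWHM
.gabor_fwhm_cycles <- 0.3024

#' Cortical decision-stage parameters
#'
#' The decision stage reads a single modulation filter, selected by its
#' temporal rate `omega` (Hz) and spectral scale `Omega` (cycles/octave), and
#' applies a collapsing threshold T(t) = b exp(-t/lambda) + a to the
#' (matched-filtered) spectral-contrast modulation trace (see
#' [modulation_filter()]); the first peak
#' above the bound is the decision, followed by the motor delay. The default
#' rate/scale (0.72 Hz, 0.54 cyc/oct) is the filter that best matched human
#' behaviour; threshold amplitudes `a`, `b` are in units of the model's
#' normalized output (baseline plateau = 1), so published values in other
#' scalings are comparable only qualitatively.
#'
#' @param omega temporal modulation rate, Hz.
#' @param Omega spectral modulation scale, cycles/octave.
#' @param a threshold asymptote (late bound).
#' @param b threshold initial elevation above `a`.
#' @param lam threshold decay time constant, seconds.
#' @param t_motor motor delay, seconds.
#' @param band frequency band (Hz) whose channels enter the decision
#'   readout; defaults to the stimulus octaves.
#' @return list of class `cortical_params`.
#' @export
cortical_params <- function(omega = 0.72, Omega = 0.54, a = 5, b = 8,
                            lam = 1.14, t_motor = 0.25,
                            band = c(380, 1900)) {
  if (a <= 0 || b < 0 || lam <= 0) stop("need a > 0, b >= 0, lam > 0")
  if (omega <= 0 || Omega <= 0) stop("omega and Omega must be positive")
  structure(list(omega = omega, Omega = Omega, a = a, b = b, lam = lam,
                 t_motor = t_motor, band = band), class = "cortical_params")
}

#' Auditory spectrogram (simplified cochleogram)
#'
#' A cochlea-like time-frequency analysis. The cochlear stage is a bank of
#' `n_channels` constant-Q, asymmetric bandpass filters (Gaussian skirts,
#' steeper above the center frequency) equally spaced on the log frequency
#' axis (default 128 channels at 24/octave from 180 Hz, spanning 5.3
#' octaves), realized by frequency-domain subband extraction so low-frequency
#' channels keep their full spectral selectivity. Each channel's analytic
#' envelope is compressed (cube root of power), sharpened by a
#' lateral-inhibition stage (positive first difference across channels,
#' half-wave rectified), smoothed by a 4 ms leaky integrator, and downsampled
#' to the output frame rate (100 Hz).
#'
#' @param wave mono waveform (numeric vector).
#' @param sample_rate sampling rate in Hz (default: `sample_rate` attribute).
#' @param n_channels number of log-spaced channels.
#' @param f_min lowest channel center frequency, Hz.
#' @param channels_per_octave channel density.
#' @param frame_rate output frame rate, Hz.
#' @param compression power compression exponent (cube-root amplitude-like).
#' @param q channel quality factor (center frequency / low-side FWHM).
#' @param asym ratio of low-side to high-side filter width (> 1: steeper
#'   above CF, as in the cochlea).
#' @param tau_integrate leaky-integration time constant, seconds.
#' @return object of class `aud_spectrogram`: list with `data` (frames x
#'   channels, nonnegative), `cf` (channel center frequencies), `t`,
#'   `frame_rate`.
#' @export
auditory_spectrogram <- function(wave,
                                 sample_rate = attr(wave, "sample_rate"),
                                 n_channels = 128, f_min = 180,
                                 channels_per_octave = 24, frame_rate = 100,
                                 compression = 1 / 3, q = 8, asym = 4,
                                 tau_integrate = 0.004) {
  if (is.null(sample_rate)) stop("sample_rate required")
  if (!length(wave)) stop("empty waveform")
  if (max(abs(wave)) > 1 + 1e-6) warning("clipped input (|x| > 1)")
  cf <- f_min * 2^((seq_len(n_channels) - 1) / channels_per_octave)
  if (max(cf) > sample_rate / 2)
    stop("channel center frequencies exceed Nyquist; raise sample_rate")

  n <- length(wave)
  nfft <- 2^ceiling(log2(n + 1))
  X <- stats::fft(c(wave, numeric(nfft - n)))
  f_bin <- (seq_len(nfft / 2) - 1) * sample_rate / nfft
  n_frames <- as.integer(floor(n / sample_rate * frame_rate))
  if (n_frames < 1) stop("waveform shorter than one output frame")

  env <- matrix(0, n_frames, n_channels)
  for (ch in seq_len(n_channels)) {
    c0 <- cf[ch]
    s_lo <- c0 / q / 2.355
    s_hi <- s_lo / asym
    # per-channel subband rate: smallest power-of-two decimation holding
    # the channel passband (zoom FFT)
    span <- 4.3 * (s_lo + s_hi) + 2 * frame_rate
    dec <- 2^floor(log2(sample_rate / max(2 * span, 4 * frame_rate)))
    m <- nfft / dec
    fs_env <- sample_rate / dec
    sel <- which(f_bin > c0 - 4.3 * s_lo - fs_env / 8 &
                 f_bin < c0 + 4.3 * s_hi + fs_env / 8)
    w <- exp(-0.5 * ((f_bin[sel] - c0) /
                       ifelse(f_bin[sel] <= c0, s_lo, s_hi))^2)
    Y <- complex(real = numeric(m))
    Y[(sel - 1) %% m + 1] <- X[sel] * w
    y <- Mod(stats::fft(Y, inverse = TRUE))[seq_len(ceiling(n / dec))] *
      2 / nfft
    e <- y^(2 * compression)  # compress (power)^compression
    a_int <- 1 - exp(-(1 / fs_env) / tau_integrate)
    e <- stats::filter(a_int * e, 1 - a_int, method = "recursive")
    k <- as.integer(round(fs_env / frame_rate))
    env[, ch] <- colMeans(matrix(e[seq_len(k * n_frames)], k, n_frames))
  }

  # lateral inhibition: ascending-frequency gradient, half-wave rectified
  lin <- env
  lin[, -1] <- env[, -1] - env[, -n_channels]
  lin[lin < 0] <- 0

  structure(list(data = lin, cf = cf, frame_rate = frame_rate,
                 t = (seq_len(n_frames) - 1) / frame_rate,
                 channels_per_octave = channels_per_octave),
            class = "aud_spectrogram")
}

#' Bin-summed energy profile of an auditory spectrogram
#'
#' Sums the time-averaged channel energies within each spectral bin of the
#' tone grid, the readout used to check that the cochleogram tracks the
#' marginal distribution. Channels are assigned to the bin of the nearest
#' tone with a half-channel upward shift (the lateral-inhibition stage puts
#' a tone's energy at the rising edge just below its frequency) and channels
#' at the spectrum edge, below the second tone, are excluded (the lowest
#' tone borders silence and collects the whole rising skirt).
#'
#' @param spec an [auditory_spectrogram()].
#' @param grid the [tone_grid()] the stimulus was built on.
#' @return numeric vector of per-bin summed energy (length `grid$n_bins`).
#' @export
bin_energy_profile <- function(spec, grid) {
  shift <- 1 / (2 * spec$channels_per_octave)
  ch_tone <- vapply(spec$cf * 2^shift, function(f)
    which.min(abs(log2(f / grid$tone_freqs))), integer(1))
  keep <- ch_tone >= 2
  prof <- colMeans(spec$data)
  as.numeric(tapply(prof[keep],
                    factor(grid$bin_of_tone[ch_tone[keep]],
                           levels = seq_len(grid$n_bins)),
                    sum))
}

#' @export
print.aud_spectrogram <- function(x, ...) {
  cat("aud_spectrogram:", nrow(x$data), "frames x", ncol(x$data),
      "channels,", format(min(x$cf)), "-", format(round(max(x$cf))),
      "Hz @", x$frame_rate, "Hz\n")
  invisible(x)
}

#' Spectral (scale) Gabor kernel
#'
#' Complex Gabor on the log-frequency axis tuned to `Omega` cycles/octave.
#' The Gaussian envelope width follows the convention FWHM = 0.3024/Omega
#' octaves, i.e. the 0.54 cyc/oct filter has a 0.56-octave full width at
#' half maximum. The real (cosine-phase, zero-phase) part is used for
#' filtering; the magnitude is the envelope.
#'
#' @param Omega scale in cycles/octave.
#' @param x log-frequency offsets in octaves at which to evaluate.
#' @return complex kernel values.
#' @export
scale_kernel <- function(Omega, x) {
  sigma <- .gabor_fwhm_cycles / (2 * sqrt(2 * log(2))) / Omega
  exp(-x^2 / (2 * sigma^2)) * exp(2i * pi * Omega * x)
}

#' Measured FWHM of the scale kernel, in octaves
#'
#' Evaluates the kernel magnitude on a fine log-frequency grid and measures
#' the width between half-maximum points.
#'
#' @param Omega scale in cycles/octave.
#' @param dx grid resolution in octaves.
#' @return full width at half maximum, octaves.
#' @export
scale_kernel_fwhm <- function(Omega, dx = 1e-4) {
  x <- seq(-6 / Omega, 6 / Omega, by = dx)
  h <- abs(scale_kernel(Omega, x))
  above <- which(h >= max(h) / 2)
  x[above[length(above)]] - x[above[1]]
}

#' Temporal (rate) kernel
#'
#' Gamma-shaped envelope t^2 exp(-3.5 omega t) modulated at `omega` Hz
#' (Q = 1 tuning), as a complex analytic kernel. Zero characteristic phase:
#' the cosine is referenced to the envelope peak, so the real part has a
#' positive main lobe and positive DC gain, normalized to 1 (a stationary
#' input passes with unit gain, so the trace plateau sits at the mean input
#' level).
#'
#' @param omega rate in Hz.
#' @param dt sampling step of the trace, seconds.
#' @param t_max kernel support, seconds (default covers the envelope decay).
#' @return complex kernel sampled at `dt`.
#' @export
rate_kernel <- function(omega, dt, t_max = NULL) {
  if (is.null(t_max)) t_max <- 4 / omega
  t <- seq(0, t_max, by = dt)
  g <- (omega * t)^2 * exp(-3.5 * omega * t)
  t_pk <- 2 / (3.5 * omega)
  h <- g * exp(2i * pi * omega * (t - t_pk))
  # unit passband gain at the tuning rate (real DC gain stays positive
  # because the cosine is referenced to the envelope peak)
  h / Mod(sum(h * exp(-2i * pi * omega * t)))
}

#' Modulation filter response
#'
#' Separable spectrotemporal filtering of an auditory spectrogram: zero-phase
#' real Gabor convolution across the log-frequency axis (the average of the
#' upward and downward quadrant filters), analytic gamma-envelope filtering
#' in time at rate `omega` (both kernels unit passband gain), then
#' aggregated
#' across frequency channels to a single trace R(t).
#'
#' Two aggregations are provided. `"contrast"` (the decision readout) is the
#' across-channel variance of the signed zero-phase response within `band`:
#' the spectral-contrast energy at the selected scale. A change in the
#' marginal makes the spectral profile peakier, so this trace deflects
#' upward after a change, ordered by change size. `"mean"` is the plain
#' channel average; because the marginal change conserves the mean channel
#' activity (the stimulus is renormalized to keep level constant), the mean
#' trace shows onset and offset responses but no average change response --
#' the summed/EEG-like readout.
#'
#' @param spec an [auditory_spectrogram()].
#' @param omega temporal rate, Hz (must be below the frame-rate Nyquist).
#' @param Omega spectral scale, cycles/octave.
#' @param aggregate `"contrast"` (across-channel variance; default) or
#'   `"mean"` (channel average).
#' @param band frequency limits (Hz) of the channels entering the aggregate;
#'   `NULL` uses all channels.
#' @param output `"real"` (signed zero-phase response; default) or
#'   `"magnitude"` (per-channel modulation envelope) for the channel matrix
#'   underlying the aggregate.
#' @param keep_channels also return the per-channel filtered matrix.
#' @return object of class `modulation_response`: list with `t`, `trace`
#'   (frequency-aggregated), `omega`, `Omega`, `frame_rate`, and optionally
#'   `channels`.
#' @export
modulation_filter <- function(spec, omega, Omega,
                              aggregate = c("contrast", "mean"),
                              band = NULL,
                              output = c("real", "magnitude"),
                              keep_channels = FALSE) {
  stopifnot(inherits(spec, "aud_spectrogram"))
  output <- match.arg(output)
  aggregate <- match.arg(aggregate)
  if (omega >= spec$frame_rate / 2)
    stop("omega above the frame-rate Nyquist")
  z <- spec$data
  cpo <- spec$channels_per_octave
  n_ch <- ncol(z)

  # spectral convolution (zero-phase, real part of the Gabor), columns
  # normalized to unit passband gain at the tuning scale (including edge
  # truncation, so boundary channels are not attenuated); the sampled
  # envelope is floored at ~1.2 channel spacings so high-scale kernels
  # remain bandpass on the discrete channel axis
  sigma <- max(.gabor_fwhm_cycles / (2 * sqrt(2 * log(2))) / Omega,
               1.2 / cpo)
  half <- min(n_ch - 1, ceiling(4 * sigma * cpo))
  kx <- (-half:half) / cpo
  ks <- exp(-kx^2 / (2 * sigma^2)) * cos(2 * pi * Omega * kx)
  Ks <- matrix(0, n_ch, n_ch)
  for (j in seq_len(n_ch)) {
    lo <- max(1, j - half); hi <- min(n_ch, j + half)
    col <- ks[(lo:hi) - j + half + 1]
    xs <- kx[(lo:hi) - j + half + 1]
    Ks[lo:hi, j] <- col / Mod(sum(col * exp(-2i * pi * Omega * xs)))
  }
  y <- z %*% Ks

  # temporal convolution with the analytic rate kernel (causal)
  dt <- 1 / spec$frame_rate
  h <- rate_kernel(omega, dt)
  n <- nrow(y); L <- length(h)
  nfft <- 2^ceiling(log2(n + L - 1))
  H <- stats::fft(c(h, complex(real = numeric(nfft - L))))
  Y <- stats::mvfft(rbind(y, matrix(0, nfft - n, n_ch)))
  r <- stats::mvfft(Y * H, inverse = TRUE)[seq_len(n), , drop = FALSE] / nfft

  vals <- if (output == "magnitude") Mod(r) else Re(r)
  sel <- if (is.null(band)) seq_len(n_ch)
         else which(spec$cf >= band[1] & spec$cf <= band[2])
  v <- vals[, sel, drop = FALSE]
  trace <- if (aggregate == "mean") rowMeans(v)
           else rowSums((v - rowMeans(v))^2) / (ncol(v) - 1)
  structure(list(t = spec$t, trace = trace, omega = omega,
                 Omega = Omega, frame_rate = spec$frame_rate,
                 aggregate = aggregate,
                 channels = if (keep_channels) vals else NULL),
            class = "modulation_response")
}

#' Summed filterbank output across the rate/scale grid
#'
#' Grand average of the frequency-MEAN modulation traces of a bank of
#' filters covering the physiological range (1-30 Hz, 0.5-8 cycles/octave):
#' the EEG-like summed cortical response. It shows onset and offset
#' responses, but the statistics change leaves no average response in it
#' (level is conserved across the change and the shape signature cancels in
#' the channel mean), in contrast to the selected filter's contrast readout.
#'
#' @param spec an [auditory_spectrogram()].
#' @param rates filter rates, Hz.
#' @param scales filter scales, cycles/octave.
#' @return list with `t` and `trace` (grand average across filters).
#' @export
modulation_filter_sum <- function(spec, rates = c(1, 2, 4, 8, 16, 30),
                                  scales = c(0.5, 1, 2, 4, 8)) {
  rates <- rates[rates < spec$frame_rate / 2]
  traces <- lapply(rates, function(w)
    vapply(scales, function(s)
      modulation_filter(spec, w, s, aggregate = "mean")$trace,
      numeric(nrow(spec$data))))
  m <- do.call(cbind, traces)
  list(t = spec$t, trace = rowMeans(m))
}

#' Matched post-filter
#'
#' Smooths a single-trial modulation trace by cross-correlation with the
#' unit-energy, mean-removed template of the trial-averaged change response
#' (centered, so peaks are not shifted by more than half the template).
#'
#' @param trace single-trial trace.
#' @param template averaged change-response shape (see
#'   [cortical_change_template()]).
#' @return filtered trace, same length (edges padded by replication).
#' @export
matched_postfilter <- function(trace, template) {
  e <- sqrt(sum(template^2))
  if (!is.finite(e) || e == 0) stop("template has zero energy")
  k <- template / e
  n <- length(trace); L <- length(k)
  xp <- c(rep(trace[1], L), trace, rep(trace[n], L))
  y <- stats::filter(xp, rev(k), method = "convolution", sides = 2)
  as.numeric(y[L + seq_len(n)])
}

#' Collapsing decision threshold
#'
#' T(t) = b exp(-t / lam) + a: elevated at stimulus onset (suppressing
#' responses to the onset transient) and decaying to the asymptote `a`. The
#' same threshold applies across all conditions.
#'
#' @param t time since stimulus onset, seconds (vectorized).
#' @param params a [cortical_params()] (or pass `a`, `b`, `lam` directly).
#' @param a,b,lam threshold parameters, overriding `params`.
#' @return threshold value(s).
#' @export
collapsing_threshold <- function(t, params = NULL, a = params$a,
                                 b = params$b, lam = params$lam) {
  b * exp(-t / lam) + a
}

#' First peak above the collapsing threshold
#'
#' Scans the trace for local maxima (3-sample neighborhood, ties broken
#' earliest) and returns the earliest one strictly above the threshold at
#' its time, plus the motor delay; NA if none.
#'
#' @param trace modulation trace.
#' @param t time grid, seconds.
#' @param threshold threshold values on the same grid.
#' @param t_motor motor delay, seconds.
#' @return list with `peak_time`, `response_time` (NA if no peak crosses).
#' @export
detect_first_peak <- function(trace, t, threshold, t_motor = 0.25) {
  n <- length(trace)
  if (n < 3)
    return(list(peak_time = NA_real_, response_time = NA_real_))
  i <- 2:(n - 1)
  is_peak <- trace[i] >= trace[i - 1] & trace[i] >= trace[i + 1] &
    (trace[i] > trace[i - 1] | trace[i] > trace[i + 1])
  cand <- i[is_peak & trace[i] > threshold[i]]
  if (!length(cand))
    return(list(peak_time = NA_real_, response_time = NA_real_))
  list(peak_time = t[cand[1]], response_time = t[cand[1]] + t_motor)
}

# full front end for one realized trial
.cortical_trace <- function(trial, params, grid, sample_rate, level_db,
                            tones_per_octave = 2) {
  seqs <- realize_trial(trial, grid, tones_per_octave = tones_per_octave)
  wave <- render_waveform(seqs, level_db = level_db,
                          sample_rate = sample_rate)
  spec <- auditory_spectrogram(wave, sample_rate)
  modulation_filter(spec, params$omega, params$Omega, band = params$band)
}

#' Baseline plateau of the selected modulation filter
#'
#' Trial-averaged value of the frequency-averaged modulation trace in a late
#' window of no-change baseline textures; used to normalize model output so
#' threshold parameters are in plateau units (plateau = 1).
#'
#' @param params a [cortical_params()].
#' @param grid a [tone_grid()].
#' @param n_trials number of baseline trials averaged.
#' @param duration trial duration, seconds.
#' @param window time window (seconds) over which the plateau is averaged.
#' @param sample_rate audio rendering rate, Hz.
#' @param level_db rendering level.
#' @param seed RNG seed.
#' @return scalar plateau value.
#' @export
cortical_plateau <- function(params = cortical_params(), grid = tone_grid(),
                             n_trials = 30, duration = 4, window = c(2, 4),
                             sample_rate = 16000, level_db = 70, seed = 1) {
  set.seed(seed)
  vals <- vapply(seq_len(n_trials), function(i) {
    p <- sample_marginal()
    seqs <- generate_chords(grid, p, duration = duration)
    wave <- render_waveform(seqs, level_db = level_db,
                            sample_rate = sample_rate)
    spec <- auditory_spectrogram(wave, sample_rate)
    mr <- modulation_filter(spec, params$omega, params$Omega,
                            band = params$band)
    mean(mr$trace[mr$t >= window[1] & mr$t <= window[2]])
  }, numeric(1))
  mean(vals)
}

#' Trial-averaged change-response template
#'
#' Averages change-aligned single-trial modulation traces over synthetic
#' change trials, extracts the segment of length 1/(2 omega) seconds
#' starting at the change, removes its mean, and returns it for use as the
#' matched post-filter.
#'
#' @param params a [cortical_params()].
#' @param grid a [tone_grid()].
#' @param n_trials trials averaged (>= 100 recommended).
#' @param change_size change size in percent.
#' @param change_time fixed change time used for the template trials, s.
#' @param sample_rate audio rendering rate, Hz.
#' @param level_db rendering level.
#' @param seed RNG seed.
#' @return numeric template vector (attribute `frame_rate`).
#' @export
cortical_change_template <- function(params = cortical_params(),
                                     grid = tone_grid(), n_trials = 100,
                                     change_size = 110, change_time = 3,
                                     sample_rate = 16000, level_db = 70,
                                     seed = 1) {
  set.seed(seed)
  frame_rate <- NULL
  acc <- NULL
  for (i in seq_len(n_trials)) {
    p <- sample_marginal()
    pair <- change_bin_pairs(grid$n_bins)[sample.int(4, 1), ]
    q <- apply_change(p, pair, change_size)
    seqs <- generate_chords(grid, p, q, change_time = change_time,
                            duration = change_time + 2)
    wave <- render_waveform(seqs, level_db = level_db,
                            sample_rate = sample_rate)
    spec <- auditory_spectrogram(wave, sample_rate)
    mr <- modulation_filter(spec, params$omega, params$Omega,
                            band = params$band)
    if (is.null(acc)) { acc <- mr$trace; frame_rate <- mr$frame_rate }
    else acc <- acc + mr$trace
  }
  avg <- acc / n_trials
  t <- (seq_along(avg) - 1) / frame_rate
  L <- max(3L, round((1 / (2 * params$omega)) * frame_rate))
  i0 <- which.min(abs(t - change_time))
  seg <- avg[i0:min(length(avg), i0 + L - 1)]
  seg <- seg - mean(seg)
  structure(seg, frame_rate = frame_rate)
}

#' Simulate the cortical model over a trial batch
#'
#' Renders each trial to audio, runs the cochleogram and the selected
#' modulation filter, normalizes by the baseline plateau, applies the
#' matched post-filter and the collapsing-threshold first-peak rule, and
#' classifies outcomes with the behavioural rules.
#'
#' @param trials a [generate_trials()] table.
#' @param params a [cortical_params()].
#' @param grid a [tone_grid()].
#' @param template matched-filter template; `NULL` builds one with
#'   [cortical_change_template()] (`template_trials` trials), `FALSE`
#'   disables post-filtering.
#' @param plateau normalization scale; `NULL` computes it with
#'   [cortical_plateau()].
#' @param sample_rate audio rendering rate, Hz.
#' @param level `"fixed"` renders all trials at 70 dB (the model has no
#'   adaptive gain stage); `"roved"` uses each trial's roved level.
#' @param window response window, seconds.
#' @param template_trials trials used to build the template.
#' @param seed seed for template/plateau construction.
#' @return a [response_records()] table.
#' @export
simulate_cortical <- function(trials, params = cortical_params(),
                              grid = tone_grid(), template = NULL,
                              plateau = NULL, sample_rate = 16000,
                              level = c("fixed", "roved"), window = 2,
                              template_trials = 100, seed = 1) {
  level <- match.arg(level)
  if (is.null(plateau))
    plateau <- cortical_plateau(params, grid, sample_rate = sample_rate,
                                seed = seed)
  if (is.null(template))
    template <- cortical_change_template(params, grid,
                                         n_trials = template_trials,
                                         sample_rate = sample_rate,
                                         seed = seed)
  resp <- vapply(seq_len(nrow(trials)), function(i) {
    lev <- if (level == "fixed") 70 else trials$level_db[i]
    mr <- .cortical_trace(trials[i, ], params, grid, sample_rate, lev)
    tr <- mr$trace / plateau
    if (!isFALSE(template)) tr <- matched_postfilter(tr, template)
    thr <- collapsing_threshold(mr$t, params)
    detect_first_peak(tr, mr$t, thr, params$t_motor)$response_time
  }, numeric(1))
  response_records(trials, resp, window = window)
}

#' Fit the cortical decision stage by grid search
#'
#' Searches (omega, Omega) x (a, b, lam) for the minimum pooled MSE of the
#' performance and false-alarm-rate curves against target curves. The
#' expensive front end (cochleogram + modulation filtering) is computed once
#' per (omega, Omega) and cached; the threshold grid reuses the traces.
#' Reaction times are emitted but not fitted.
#'
#' @param trials trial batch the targets were measured on.
#' @param target list with `perf` and `fa` curves (as in [fit_dual()]).
#' @param grid named list of candidate values for `omega`, `Omega`, `a`,
#'   `b`, `lam`.
#' @param tone_grid_ a [tone_grid()].
#' @param sample_rate audio rendering rate, Hz.
#' @param n_time_bins change-time bins for the performance curve.
#' @param fa_dt false-alarm bin width, seconds.
#' @param t_motor motor delay, seconds.
#' @param template_trials trials for each template.
#' @param seed seed for template/plateau construction.
#' @return list of class `cortical_fit`: `params`, `mse`, `mse_perf`,
#'   `mse_fa`, `on_boundary`, `table`.
#' @export
fit_cortical <- function(trials, target,
                         grid = list(omega = 0.72,
                                     Omega = c(0.35, 0.54, 0.8),
                                     a = c(4, 5, 6), b = c(6, 8, 10),
                                     lam = 1.14),
                         tone_grid_ = tone_grid(), sample_rate = 16000,
                         n_time_bins = 4, fa_dt = 0.5, t_motor = 0.25,
                         template_trials = 50, seed = 1) {
  stopifnot(all(c("omega", "Omega", "a", "b", "lam") %in% names(grid)))
  score <- function(records) {
    perf <- performance_table(records, n_time_bins, localized_only = TRUE)
    fa <- instantaneous_fa_rate(records, dt = fa_dt,
                                t_max = max(target$fa$t))
    key <- paste(perf$change_size, perf$bin)
    tkey <- paste(target$perf$change_size, target$perf$bin)
    mp <- perf$performance[match(tkey, key)]
    ok <- !is.na(mp) & !is.na(target$perf$performance)
    mse_p <- mean((mp[ok] - target$perf$performance[ok])^2)
    mf <- fa$rate[match(target$fa$t, fa$t)]
    okf <- !is.na(mf) & !is.na(target$fa$rate)
    mse_f <- mean((mf[okf] - target$fa$rate[okf])^2)
    c(mse_p, mse_f)
  }

  rows <- list()
  best <- NULL
  for (w in grid$omega) for (s in grid$Omega) {
    p0 <- cortical_params(omega = w, Omega = s, t_motor = t_motor)
    plateau <- cortical_plateau(p0, tone_grid_, sample_rate = sample_rate,
                                seed = seed)
    template <- cortical_change_template(p0, tone_grid_,
                                         n_trials = template_trials,
                                         sample_rate = sample_rate,
                                         seed = seed)
    traces <- lapply(seq_len(nrow(trials)), function(i) {
      mr <- .cortical_trace(trials[i, ], p0, tone_grid_, sample_rate, 70)
      list(t = mr$t, tr = matched_postfilter(mr$trace / plateau, template))
    })
    for (a in grid$a) for (b in grid$b) for (lam in grid$lam) {
      resp <- vapply(traces, function(x)
        detect_first_peak(x$tr, x$t,
                          collapsing_threshold(x$t, a = a, b = b, lam = lam),
                          t_motor)$response_time, numeric(1))
      sc <- score(response_records(trials, resp))
      row <- data.frame(omega = w, Omega = s, a = a, b = b, lam = lam,
                        mse_perf = sc[1], mse_fa = sc[2],
                        mse = sc[1] + sc[2])
      rows[[length(rows) + 1]] <- row
      if (is.null(best) || row$mse < best$mse) best <- row
    }
  }
  tab <- do.call(rbind, rows)
  on_edge <- vapply(c("omega", "Omega", "a", "b", "lam"), function(nm)
    length(grid[[nm]]) > 1 && best[[nm]] %in% range(grid[[nm]]), logical(1))
  structure(list(
    params = cortical_params(best$omega, best$Omega, best$a, best$b,
                             best$lam, t_motor),
    mse = best$mse, mse_perf = best$mse_perf, mse_fa = best$mse_fa,
    on_boundary = on_edge, table = tab), class = "cortical_fit")
}

#' @export
print.cortical_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "cortical fit: omega=%.3g Omega=%.3g a=%.3g b=%.3g lam=%.3g (MSE %.4g)\n",
    p$omega, p$Omega, p$a, p$b, p$lam, x$mse))
  if (any(x$on_boundary))
    cat("note: optimum on grid boundary for",
        paste(names(x$on_boundary)[x$on_boundary], collapse = ", "), "\n")
  invisible(x)
}
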