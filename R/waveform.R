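#' Render a chord sequence to an audio waveform
#'
#' Each tone is a 30 ms sinusoid gated with raised-cosine on/off ramps;
#' simultaneous tones within a chord sum linearly. The presentation level is
#' a per-trial scalar: a single tone at `ref_db` dB has unit peak amplitude,
#' so dB values are relative full scale, not calibrated SPL (the behavioural
#' design roves level over 60-80 dB to defeat absolute-level strategies).
#'
#' @param seq a [generate_chords()] result.
#' @param level_db presentation level in dB re full scale at `ref_db`.
#' @param sample_rate audio sampling rate in Hz (must exceed twice the
#'   highest tone frequency).
#' @param ramp raised-cosine ramp duration in seconds at each tone edge.
#' @param ref_db level mapped to unit tone amplitude.
#' @return numeric vector of samples, length `n_chords * chord_dur *
#'   sample_rate`, with attribute `sample_rate`.
#' @export
render_waveform <- function(seq, level_db = 70, sample_rate = 16000,
                            ramp = 0.005, ref_db = 100) {
  stopifnot(inherits(seq, "chord_sequence"))
  f_max <- max(seq$grid$tone_freqs)
  if (sample_rate < 2 * f_max)
    stop("sample_rate ", sample_rate, " violates Nyquist for ", f_max, " Hz")
  if (2 * ramp > seq$chord_dur) stop("ramps longer than the chord")

  n_per <- round(seq$chord_dur * sample_rate)
  amp <- 10^((level_db - ref_db) / 20)
  t_loc <- (seq_len(n_per) - 1) / sample_rate
  gate <- rep(1, n_per)
  n_r <- round(ramp * sample_rate)
  if (n_r > 0) {
    r <- 0.5 - 0.5 * cos(pi * (seq_len(n_r) - 0.5) / n_r)
    gate[seq_len(n_r)] <- r
    gate[n_per + 1 - seq_len(n_r)] <- r
  }

  wave <- numeric(seq$n_chords * n_per)
  for (c in seq_len(seq$n_chords)) {
    tones <- seq$chords[[c]]
    if (!length(tones)) next
    freqs <- seq$grid$tone_freqs[tones]
    t_abs <- (c - 1) * seq$chord_dur + t_loc
    s <- gate * rowSums(sin(2 * pi * outer(t_abs, freqs)))
    wave[(c - 1) * n_per + seq_len(n_per)] <- amp * s
  }
  attr(wave, "sample_rate") <- sample_rate
  wave
}

#' Write a mono waveform as 32-bit float WAV
#'
#' Minimal RIFF/WAVE writer (IEEE float, format code 3).
#'
#' @param wave numeric sample vector.
#' @param path output file path.
#' @param sample_rate sampling rate in Hz; defaults to the waveform's
#'   `sample_rate` attribute.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate = attr(wave, "sample_rate")) {
  if (is.null(sample_rate)) stop("sample_rate required")
  n <- length(wave)
  data_bytes <- 4L * n
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(3L); w16(1L)                      # IEEE float, mono
  w32(as.integer(sample_rate)); w32(as.integer(sample_rate) * 4L)
  w16(4L); w16(32L)
  writeChar("data", con, eos = NULL); w32(data_bytes)
  writeBin(as.numeric(wave), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono 32-bit float or 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return numeric sample vector with attribute `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  hdr <- readChar(con, 4); r32()
  if (!identical(hdr, "RIFF") || !identical(readChar(con, 4), "WAVE"))
    stop("not a RIFF/WAVE file")
  fmt <- NULL; srate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) stop("no data chunk found")
    size <- r32()
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size = 2, endian = "little")
      nch <- readBin(con, "integer", size = 2, endian = "little")
      srate <- r32(); r32()
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", n = size - 16)
      if (nch != 1) stop("only mono WAV supported")
      attr(fmt, "bits") <- bits
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      bits <- attr(fmt, "bits")
      if (fmt == 3 && bits == 32) {
        wave <- readBin(con, "numeric", n = size / 4, size = 4,
                        endian = "little")
      } else if (fmt == 1 && bits == 16) {
        wave <- readBin(con, "integer", n = size / 2, size = 2,
                        endian = "little") / 32768
      } else stop("unsupported WAV format")
      attr(wave, "sample_rate") <- srate
      return(wave)
    } else {
      readBin(con, "raw", n = size + (size %% 2))
    }
  }
}
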