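#' Specification of an ABA triplet stimulus
#'
#' Describes the classic auditory-streaming stimulus: repeating triplets of
#' three equally spaced pure tones, low-high-low (A-B-A), followed by a
#' silent slot, so that each triplet occupies four equal onset slots. The B
#' tone sits `semitone_sep` semitones above the A (base) tone.
#'
#' @param base_freq A-tone frequency in Hz.
#' @param semitone_sep A-to-B separation in semitones (typically 3, 6 or 12).
#' @param tone_dur duration of each tone in seconds.
#' @param ramp_dur duration of the raised-cosine onset/offset ramps, seconds.
#' @param onset_step time between successive tone onsets within a triplet,
#'   seconds.
#' @param triplet_period triplet onset-to-onset period, seconds. With the
#'   defaults the fourth 120 ms slot is silent (ABA-).
#' @param repetitions number of triplets.
#' @param sample_rate sampling rate in Hz.
#' @param level peak linear amplitude of each tone (full scale = 1).
#'
#' @return An object of class `stimulus_spec`.
#' @export
#' @examples
#' spec <- stimulus_spec(semitone_sep = 6, repetitions = 10)
#' sig <- generate_aba(spec)
#' duration(sig)
stimulus_spec <- function(base_freq = 500, semitone_sep = 6,
                          tone_dur = 0.050, ramp_dur = 0.010,
                          onset_step = 0.120, triplet_period = 0.480,
                          repetitions = 100, sample_rate = 8000,
                          level = 0.5) {
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  if (tone_dur < 0 || ramp_dur < 0 || onset_step <= 0 || triplet_period <= 0)
    stop("durations must be non-negative and steps positive", call. = FALSE)
  if (repetitions < 0) stop("repetitions must be >= 0", call. = FALSE)
  if (tone_dur > onset_step)
    stop("tone_dur must fit within onset_step", call. = FALSE)
  if (3 * onset_step > triplet_period)
    stop("three onset steps must fit within triplet_period", call. = FALSE)
  structure(list(base_freq = base_freq, semitone_sep = semitone_sep,
                 tone_dur = tone_dur, ramp_dur = ramp_dur,
                 onset_step = onset_step, triplet_period = triplet_period,
                 repetitions = repetitions, sample_rate = sample_rate,
                 level = level),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("ABA stimulus: A = %g Hz, B = %g Hz (%g st), %d reps, %g s\n",
              x$base_freq, b_freq(x), x$semitone_sep, x$repetitions,
              x$repetitions * x$triplet_period))
  invisible(x)
}

#' B-tone frequency of an ABA stimulus
#'
#' @param spec a [stimulus_spec()].
#' @return frequency in Hz: `base_freq * 2^(semitone_sep / 12)`.
#' @export
b_freq <- function(spec) spec$base_freq * 2^(spec$semitone_sep / 12)

#' An audio signal
#'
#' @param samples numeric vector of linear amplitudes.
#' @param sample_rate sampling rate in Hz.
#' @return object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_signal")
}

#' Duration of an audio signal in seconds
#' @param signal an [audio_signal()].
#' @export
duration <- function(signal) length(signal$samples) / signal$sample_rate

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("audio_signal: %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate, duration(x)))
  invisible(x)
}

# one ramped tone as a sample vector
ramped_tone <- function(freq, spec) {
  n <- round(spec$tone_dur * spec$sample_rate)
  if (n == 0) return(numeric(0))
  t <- (seq_len(n) - 1) / spec$sample_rate
  env <- rep(1, n)
  nr <- round(spec$ramp_dur * spec$sample_rate)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    env[seq_len(nr)] <- ramp
    env[n + 1 - seq_len(nr)] <- ramp
  }
  spec$level * env * sin(2 * pi * freq * t)
}

#' Synthesize an ABA triplet sequence
#'
#' Generates `repetitions` triplets; within each `triplet_period` the A tone
#' starts at offset 0, the B tone at `onset_step`, and the second A at
#' `2 * onset_step`. Each tone carries raised-cosine onset/offset ramps; all
#' remaining time is exact silence.
#'
#' @param spec a [stimulus_spec()].
#' @return an [audio_signal()] of duration `repetitions * triplet_period`.
#' @export
generate_aba <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$semitone_sep <= 0)
    stop("semitone_sep must be positive", call. = FALSE)
  sr <- spec$sample_rate
  n_total <- round(spec$repetitions * spec$triplet_period * sr)
  x <- numeric(n_total)
  if (spec$repetitions == 0) return(audio_signal(x, sr))
  a <- ramped_tone(spec$base_freq, spec)
  b <- ramped_tone(b_freq(spec), spec)
  n_tone <- length(a)
  for (rep_i in seq_len(spec$repetitions) - 1) {
    t0 <- rep_i * spec$triplet_period
    for (k in 0:2) {
      i0 <- round((t0 + k * spec$onset_step) * sr)
      idx <- i0 + seq_len(n_tone)
      idx <- idx[idx <= n_total]
      tone <- if (k == 1) b else a
      x[idx] <- x[idx] + tone[seq_along(idx)]
    }
  }
  audio_signal(x, sr)
}

#' Write an audio signal as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (mono, PCM 16-bit). Samples are clipped to
#' \[-1, 1\] and quantized to 16 bits.
#'
#' @param signal an [audio_signal()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- pmax(-1, pmin(1, signal$samples))
  pcm <- as.integer(round(x * 32767))
  sr <- as.integer(signal$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")     # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path path to a mono or multi-channel PCM WAV file; channels are
#'   averaged to mono.
#' @return an [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  sr <- NULL; n_chan <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("malformed WAV file: ", path, call. = FALSE)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported", call. = FALSE)
      n_chan <- fmt[2]
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit WAV supported", call. = FALSE)
      extra <- sz - 16L
      if (extra > 0) invisible(readBin(con, raw(), n = extra))
    } else if (identical(id, "data")) {
      if (is.null(sr)) stop("malformed WAV file: data before fmt", call. = FALSE)
      pcm <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                     endian = "little", signed = TRUE)
      x <- pcm / 32767
      if (n_chan > 1L) {
        x <- colMeans(matrix(x, nrow = n_chan))
      }
      return(audio_signal(x, sr))
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
}
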