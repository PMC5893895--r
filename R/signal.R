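#' Sampled mono signal
#'
#' Container for a uniformly sampled real-valued waveform. Besides the raw
#' samples and the sampling rate, a signal may carry a per-sample
#' `ratio_trajectory` (the instantaneous interval ratio of a two-tone
#' stimulus, e.g. glissando frequency over fixed frequency) and the base
#' frequency of the stimulus it was synthesized from. Sample `n` (0-based)
#' corresponds to time `t = n / sample_rate`.
#'
#' @param samples numeric vector of waveform samples.
#' @param sample_rate sampling rate in samples per second (> 0).
#' @param ratio_trajectory optional numeric vector, same length as
#'   `samples`, giving the instantaneous interval ratio at each sample.
#' @param base_frequency optional reference frequency (Hz) of the stimulus.
#'
#' @return An object of class `tone_signal`: a list with elements
#'   `samples`, `sample_rate`, `ratio_trajectory`, `base_frequency`.
#' @export
tone_signal <- function(samples, sample_rate, ratio_trajectory = NULL,
                        base_frequency = NULL) {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  if (!is.null(ratio_trajectory)) {
    if (length(ratio_trajectory) != length(samples))
      stop("`ratio_trajectory` must have the same length as `samples` (",
           length(ratio_trajectory), " vs ", length(samples), ")")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         ratio_trajectory = ratio_trajectory, base_frequency = base_frequency),
    class = "tone_signal")
}

#' @export
print.tone_signal <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate
  cat(sprintf("<tone_signal> %d samples @ %g Hz (%.4g s)\n",
              length(x$samples), x$sample_rate, dur))
  if (!is.null(x$base_frequency))
    cat(sprintf("  base frequency: %g Hz\n", x$base_frequency))
  if (!is.null(x$ratio_trajectory))
    cat(sprintf("  ratio trajectory: %.6g .. %.6g\n",
                x$ratio_trajectory[1],
                x$ratio_trajectory[length(x$ratio_trajectory)]))
  invisible(x)
}

#' @export
length.tone_signal <- function(x) length(x$samples)

#' Duration of a signal in seconds
#' @param signal a [tone_signal].
#' @return duration in seconds.
#' @export
signal_duration <- function(signal) length(signal$samples) / signal$sample_rate

check_tone_spec <- function(frequency, sample_rate, duration) {
  if (frequency < 0) stop("frequency must be non-negative")
  if (frequency >= sample_rate / 2)
    stop("frequency ", frequency, " Hz violates the Nyquist limit (",
         sample_rate / 2, " Hz at ", sample_rate, " samples/s)")
  if (duration <= 0) stop("duration must be positive")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  invisible(TRUE)
}

#' Synthesize a pure tone
#'
#' `samples[n] = amplitude * sin(2 * pi * frequency * n / sample_rate + phase)`
#' with 0-based sample index `n`.
#'
#' @param frequency tone frequency in Hz; must lie below the Nyquist
#'   frequency `sample_rate / 2`.
#' @param duration duration in seconds (> 0); the number of samples is
#'   `round(duration * sample_rate)`.
#' @param sample_rate samples per second.
#' @param amplitude peak amplitude (default 1).
#' @param phase initial phase in radians (default 0).
#' @return A [tone_signal].
#' @examples
#' s <- pure_tone(400, duration = 1, sample_rate = 8000)
#' length(s$samples)  # 8000
#' @export
pure_tone <- function(frequency, duration, sample_rate = 8000,
                      amplitude = 1, phase = 0) {
  check_tone_spec(frequency, sample_rate, duration)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  tone_signal(amplitude * sin(2 * pi * frequency * t + phase), sample_rate,
              base_frequency = frequency)
}

#' Mix two signals to mono
#'
#' Per-sample arithmetic mean of the two channels (the convention most
#' stereo-to-mono editor conversions use). Both inputs must share length and
#' sampling rate. The `ratio_trajectory` is inherited from whichever input
#' carries one (the first, if both do); `base_frequency` likewise.
#'
#' @param left,right [tone_signal] objects of equal length and rate.
#' @return A mono [tone_signal].
#' @export
mix_mono <- function(left, right) {
  if (length(left$samples) != length(right$samples))
    stop("channel length mismatch: ", length(left$samples), " vs ",
         length(right$samples))
  if (left$sample_rate != right$sample_rate)
    stop("sample rate mismatch: ", left$sample_rate, " vs ",
         right$sample_rate)
  traj <- left$ratio_trajectory
  if (is.null(traj)) traj <- right$ratio_trajectory
  bf <- left$base_frequency
  if (is.null(bf)) bf <- right$base_frequency
  tone_signal((left$samples + right$samples) / 2, left$sample_rate,
              ratio_trajectory = traj, base_frequency = bf)
}

#' Synthesize a mistuned two-tone interval
#'
#' Mono mixture of a base tone at `base_frequency` (f1) and a second tone at
#' `(ratio_num / ratio_den) * f1 + epsilon`. With `epsilon = 0` the interval
#' is perfectly tuned and the waveform is exactly periodic with fundamental
#' `gcd`-frequency `f1 / ratio_den` (for a reduced ratio). Small `epsilon`
#' produces beats: first-order amplitude beats near the unison, second-order
#' "beats of mistuned consonances" (a drifting vibration pattern at rate
#' `ratio_den * epsilon`) for wider intervals.
#'
#' @param base_frequency f1 in Hz.
#' @param ratio_num,ratio_den small positive integers defining the interval
#'   p/q; need not be reduced.
#' @param epsilon mistuning in Hz (may be 0 or negative).
#' @param duration seconds.
#' @param sample_rate samples per second.
#' @param amplitude per-tone amplitude before mixing.
#' @return A mono [tone_signal] carrying `base_frequency` and a `mistuning`
#'   attribute (list `p`, `q`, `epsilon` with the ratio reduced).
#' @examples
#' # the mistuned fifth: 400 and 603 Hz
#' s <- mistuned_interval(400, 3, 2, epsilon = 3, duration = 1)
#' @export
mistuned_interval <- function(base_frequency, ratio_num, ratio_den,
                              epsilon = 0, duration = 1, sample_rate = 8000,
                              amplitude = 1) {
  if (ratio_num < 1 || ratio_den < 1 ||
      ratio_num != round(ratio_num) || ratio_den != round(ratio_den))
    stop("ratio_num and ratio_den must be positive integers")
  f2 <- (ratio_num / ratio_den) * base_frequency + epsilon
  a <- pure_tone(base_frequency, duration, sample_rate, amplitude)
  b <- pure_tone(f2, duration, sample_rate, amplitude)
  out <- mix_mono(a, b)
  g <- gcd_int(ratio_num, ratio_den)
  attr(out, "mistuning") <- list(p = ratio_num / g, q = ratio_den / g,
                                 epsilon = epsilon)
  out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Linear chirp
#'
#' Sine sweep whose instantaneous frequency is linear in time from `f_start`
#' at t = 0 to `f_end` at t = `duration`. The phase is the continuous
#' integral of the frequency law,
#' `phi(t) = 2*pi*(f_start*t + (f_end - f_start)*t^2 / (2*duration))`,
#' so the waveform has no phase discontinuities.
#'
#' @inheritParams pure_tone
#' @param f_start,f_end sweep endpoints in Hz (either direction; both below
#'   Nyquist).
#' @return A [tone_signal].
#' @export
linear_chirp <- function(f_start, f_end, duration, sample_rate = 8000,
                         amplitude = 1, phase = 0) {
  check_tone_spec(f_start, sample_rate, duration)
  check_tone_spec(f_end, sample_rate, duration)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  ph <- 2 * pi * (f_start * t + (f_end - f_start) * t^2 / (2 * duration))
  tone_signal(amplitude * sin(ph + phase), sample_rate)
}

#' Glissando-against-fixed-tone stimulus
#'
#' The octave-sweep stimulus: a linear chirp from `f_start` to `f_end` mixed
#' (mono, per-sample mean) with a fixed pure tone. The returned signal
#' carries a `ratio_trajectory` with the instantaneous interval ratio
#' `f_gliss(n) / fixed_frequency`, where
#' `f_gliss(n) = f_start + (f_end - f_start) * n / (N - 1)`.
#'
#' Defaults reproduce the octave-spanning sweep: 360 to 840 Hz over 6 s
#' against a fixed 400 Hz tone at 8000 samples/s, so the ratio axis runs
#' 0.9 to 2.1.
#'
#' @param f_start,f_end chirp endpoints in Hz.
#' @param fixed_frequency frequency of the fixed tone in Hz (> 0).
#' @param duration seconds.
#' @param sample_rate samples per second.
#' @param amplitude per-channel amplitude before mixing.
#' @return A mono [tone_signal] with `ratio_trajectory` and
#'   `base_frequency = fixed_frequency`.
#' @examples
#' g <- glissando_mix()
#' range(g$ratio_trajectory)  # 0.9 2.1
#' @export
glissando_mix <- function(f_start = 360, f_end = 840, fixed_frequency = 400,
                          duration = 6, sample_rate = 8000, amplitude = 1) {
  if (fixed_frequency <= 0) stop("fixed_frequency must be positive")
  chirp <- linear_chirp(f_start, f_end, duration, sample_rate, amplitude)
  fixed <- pure_tone(fixed_frequency, duration, sample_rate, amplitude)
  n <- length(chirp$samples)
  fg <- if (n == 1L) f_start else
    f_start + (f_end - f_start) * (seq_len(n) - 1) / (n - 1)
  chirp$ratio_trajectory <- fg / fixed_frequency
  out <- mix_mono(chirp, fixed)
  out$base_frequency <- fixed_frequency
  out
}

# ---- file formats ----------------------------------------------------------

#' Read and write signals
#'
#' Two plain interchange formats are supported:
#' * `"text"`: one decimal sample per line, with an optional leading header
#'   line `# rate=<Hz>`. Writing always emits the header; a file without one
#'   is read at `default_rate`. Text round-trips are exact.
#' * `"wav"`: standard RIFF 16-bit PCM mono. Samples are clipped to
#'   \[-1, 1\] and quantized to 16 bits, so a round-trip is exact only up to
#'   one quantization step (2^-15).
#'
#' @param path file path.
#' @param format `"auto"` (by file extension), `"text"` or `"wav"`.
#' @param default_rate sampling rate assumed for headerless text files.
#' @return `read_signal` returns a [tone_signal]; `write_signal` returns
#'   `path` invisibly.
#' @export
read_signal <- function(path, format = c("auto", "text", "wav"),
                        default_rate = 8000) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "text"
  if (format == "wav") return(read_wav(path))
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty signal file: ", path)
  rate <- default_rate
  header <- grepl("^\\s*#", lines)
  for (h in lines[header]) {
    m <- regmatches(h, regexec("rate\\s*=\\s*([0-9.eE+-]+)", h))[[1]]
    if (length(m) == 2L) rate <- as.numeric(m[2])
  }
  body_idx <- which(!header & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) stop("no samples in signal file: ", path)
  vals <- suppressWarnings(as.numeric(trimws(lines[body_idx])))
  if (anyNA(vals)) {
    bad <- body_idx[which(is.na(vals))[1]]
    stop("cannot parse sample at line ", bad, " of ", path, ": '",
         lines[bad], "'")
  }
  tone_signal(vals, rate)
}

#' @rdname read_signal
#' @param signal a [tone_signal] to write.
#' @export
write_signal <- function(signal, path, format = c("auto", "text", "wav")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "text"
  if (format == "wav") return(write_wav(signal, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate=%.10g", signal$sample_rate), con)
  writeLines(sprintf("%.17g", signal$samples), con)
  invisible(path)
}

write_wav <- function(signal, path) {
  x <- pmax(pmin(signal$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  rate <- as.integer(round(signal$sample_rate))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")    # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

read_wav <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0) stop("empty signal file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("unsupported WAV encoding (not PCM): ", path)
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, size = 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      invisible(readBin(con, "raw", max(0L, size - 16L)))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV (data before fmt): ", path)
      if (bits != 16L) stop("unsupported WAV bit depth: ", bits)
      samples <- readBin(con, "integer", size %/% 2L, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
  }
  if (is.null(samples)) stop("malformed WAV (no data chunk): ", path)
  if (!is.null(channels) && channels != 1L)
    stop("only mono WAV files are supported (got ", channels, " channels)")
  tone_signal(samples / 32767, rate)
}
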