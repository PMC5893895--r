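# FFT-based DSP helpers shared by the beat analysis.

# Discrete analytic signal (Hilbert transform by spectral one-siding).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Brick-wall FFT low-pass at `cutoff` Hz.
fft_lowpass <- function(x, sample_rate, cutoff) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / n * sample_rate
  freqs <- pmin(freqs, sample_rate - freqs)   # two-sided
  X[freqs > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

# Exact sinc upsampling of a band-limited signal by integer `factor`
# (zero-padding in the frequency domain).
fft_upsample <- function(x, factor) {
  n <- length(x)
  X <- stats::fft(x)
  m <- n * factor
  Y <- complex(m)
  half <- floor(n / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half >= 1) Y[(m - (n - half - 2)):m] <- X[(half + 2):n]
  if (n %% 2 == 0) {  # split the Nyquist bin
    Y[half + 1] <- X[half + 1] / 2
    Y[m - half + 1] <- X[half + 1] / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) * factor / m
}

# Pearson correlation between `probe` and every length-W window of `series`
# starting at offsets 0..(length(series) - W); FFT cross-correlation plus
# running sums.
sliding_cor <- function(probe, series) {
  w <- length(probe)
  n <- length(series)
  if (n < w) stop("series shorter than probe")
  n_off <- n - w + 1L
  m <- stats::nextn(n + w, 2)
  pf <- stats::fft(c(rev(probe), numeric(m - w)))
  sf <- stats::fft(c(series, numeric(m - n)))
  xc <- Re(stats::fft(pf * sf, inverse = TRUE) / m)
  s_xy <- xc[w:(w + n_off - 1L)]                    # sum(probe * window)
  cs <- cumsum(c(0, series))
  cs2 <- cumsum(c(0, series^2))
  s_y <- cs[(w + 1L):(n + 1L)] - cs[1:n_off]
  s_y2 <- cs2[(w + 1L):(n + 1L)] - cs2[1:n_off]
  mp <- mean(probe)
  sp <- sum((probe - mp)^2)
  num <- s_xy - mp * s_y
  den <- sqrt(sp * pmax(s_y2 - s_y^2 / w, 0))
  r <- num / den
  r[!is.finite(r)] <- 0
  r
}

#' First-order (amplitude-envelope) beat rate
#'
#' Extracts the amplitude envelope as the magnitude of the analytic signal,
#' low-passes it at `cutoff` Hz to isolate perceptual-range amplitude
#' modulation from the tone structure itself, and counts envelope maxima:
#' the rate is `(n_maxima - 1) / (t_last - t_first)` over the trimmed
#' interior of the signal (robust to edge effects of the Hilbert
#' transform). Two near-equal tones f1 and f1 + delta beat at delta Hz;
#' wider mistuned intervals (octave, fifth, ...) have an essentially flat
#' envelope and return `NA` with `flat = TRUE` — their beating is
#' second-order, see [pattern_beat_rate].
#'
#' @param signal a [tone_signal].
#' @param cutoff envelope low-pass cutoff in Hz (default 50: above any beat
#'   rate of interest, below the frequency separation of distinct tones).
#' @param depth_threshold minimum relative modulation depth
#'   `(max - min) / mean` of the smoothed envelope for beating to be
#'   declared present (default 0.1).
#' @param trim fraction of the signal discarded at each end (default 0.05).
#' @return A list of class `beat_report`: `first_order_rate` (Hz, rounded
#'   to 0.1; `NA` when flat), `raw_rate`, `flat` (logical), `n_maxima`,
#'   `method`.
#' @export
envelope_beat_rate <- function(signal, cutoff = 50, depth_threshold = 0.1,
                               trim = 0.05) {
  x <- signal$samples
  fs <- signal$sample_rate
  if (length(x) < 2 * fs / max(cutoff, 1))
    stop("signal too short to resolve envelope beating")
  env <- Mod(analytic_signal(x))
  env_lp <- fft_lowpass(env, fs, cutoff)
  n <- length(env_lp)
  keep <- seq.int(max(1L, floor(n * trim)), ceiling(n * (1 - trim)))
  e <- env_lp[keep]
  depth <- (max(e) - min(e)) / mean(e)
  if (depth < depth_threshold) {
    return(structure(list(first_order_rate = NA_real_, raw_rate = NA_real_,
                          flat = TRUE, n_maxima = 0L,
                          method = "analytic_envelope+lowpass"),
                     class = "beat_report"))
  }
  mid <- min(e) + 0.5 * (max(e) - min(e))
  is_max <- which(diff(sign(diff(e))) == -2) + 1L
  is_max <- is_max[e[is_max] > mid]
  if (length(is_max) < 2L)
    stop("fewer than two envelope maxima: cannot estimate a beat rate")
  t_max <- (keep[is_max] - 1) / fs
  raw <- (length(is_max) - 1) / (t_max[length(t_max)] - t_max[1])
  structure(list(first_order_rate = round(raw, 1), raw_rate = raw,
                 flat = FALSE, n_maxima = length(is_max),
                 method = "analytic_envelope+lowpass"),
            class = "beat_report")
}

#' Second-order (vibration-pattern) beat rate
#'
#' Rate at which the waveform's vibration pattern recurs: the reciprocal of
#' the smallest positive lag T* at which a probe window drawn from the
#' signal correlates (Pearson) at `threshold` or better with the
#' correspondingly delayed signal. For a two-tone mixture mistuned by
#' epsilon from a reduced ratio p/q, the pattern recurs every `1/(q *
#' epsilon)` seconds, reproducing the classical rates epsilon (octave),
#' 2*epsilon (fifth), 3*epsilon (fourth).
#'
#' The signal is sinc-upsampled (`upsample`-fold) before the lag search so
#' that carrier alignment, rather than sample quantization, limits the
#' attainable correlation. Around each true recurrence time the qualifying
#' correlation maxima form a narrow cluster (a few carrier-aligned lags
#' wide); clusters are split at gaps above 0.02 s and T* is the
#' best-correlated lag of the first cluster. A perfectly tuned interval is
#' exactly periodic at its gcd fundamental, so its qualifying lags form a
#' dense comb over the whole search range rather than isolated clusters:
#' when the first cluster spans more than 20% of the range, the waveform
#' period is read off the comb spacing instead and the result is flagged
#' `tuned`.
#'
#' @param signal a [tone_signal]; its `base_frequency` (or `f1`) sets the
#'   probe length.
#' @param probe_periods probe window length in periods of f1 (default 20:
#'   long enough that the two tones are near-orthogonal over the window,
#'   which the correlation analysis of spurious alignments requires).
#' @param f1 carrier/base frequency in Hz; defaults to the signal's
#'   `base_frequency`, else the dominant spectral component.
#' @param search_range lag search interval in seconds (default
#'   `c(0.05, 1.5)`).
#' @param threshold minimum self-correlation for a pattern recurrence
#'   (default 0.9995). A true pattern recurrence aligns both tones
#'   simultaneously (1 - r of order 1e-5 after sub-sample refinement),
#'   whereas the best "compromise" lags — where the two tones nearly but
#'   not jointly align — stay at 1 - r of roughly 5e-4 or worse; the
#'   threshold sits between the two regimes.
#' @param upsample integer sinc-upsampling factor (default 8).
#' @param probe_at probe start position in seconds (default 0.1).
#' @return A list of class `beat_report`: `pattern_rate` (Hz, rounded to
#'   0.1), `raw_rate`, `recurrence_time` (T*, s), `tuned` (logical),
#'   `best_correlation`, `method`.
#' @export
pattern_beat_rate <- function(signal, probe_periods = 20, f1 = NULL,
                              search_range = c(0.05, 1.5),
                              threshold = 0.9995,
                              upsample = 8, probe_at = 0.1) {
  fs <- signal$sample_rate
  x <- signal$samples
  if (is.null(f1)) f1 <- signal$base_frequency
  if (is.null(f1)) f1 <- dominant_frequency(x, fs)
  need <- probe_at + search_range[2] + probe_periods / f1
  if (length(x) / fs < need)
    stop("signal too short: need at least ", signif(need, 3),
         " s for probe position plus maximum search lag")
  fsu <- fs * upsample
  xu <- fft_upsample(x, upsample)
  w <- max(8L, round(probe_periods / f1 * fsu))
  p0 <- round(probe_at * fsu) + 1L
  max_lag <- round(search_range[2] * fsu)
  probe <- xu[p0:(p0 + w - 1L)]
  series <- xu[p0:min(length(xu), p0 + max_lag + w - 1L)]
  r <- sliding_cor(probe, series)          # r[i]: lag (i-1) samples
  lag_s <- (seq_along(r) - 1) / fsu
  in_range <- lag_s >= search_range[1] & lag_s <= search_range[2]
  loc_max <- c(FALSE, diff(sign(diff(r))) == -2, FALSE)
  cand <- which(loc_max & in_range)
  if (length(cand) == 0L)
    stop("no correlation maxima in the search range")
  # sub-sample (parabolic) refinement of each candidate maximum, so lag
  # quantization does not depress the attainable correlation
  ym <- r[cand - 1L]; y0 <- r[cand]; yp <- r[cand + 1L]
  denom <- ym - 2 * y0 + yp
  off <- ifelse(abs(denom) > 0, 0.5 * (ym - yp) / denom, 0)
  off <- pmax(pmin(off, 0.5), -0.5)
  r_ref <- y0 - 0.25 * (ym - yp) * off
  lag_ref <- lag_s[cand] + off / fsu
  qual <- which(r_ref >= threshold)
  if (length(qual) == 0L) {
    stop("no waveform self-similarity above ", threshold,
         " in the search range (best correlation ",
         signif(max(r_ref), 4), ")")
  }
  # group qualifying maxima into recurrence clusters
  cl <- cumsum(c(TRUE, diff(lag_ref[qual]) > 0.02))
  first <- qual[cl == 1L]
  span <- diff(range(lag_ref[first]))
  tuned <- FALSE
  if (span > 0.2 * diff(search_range) && length(first) >= 3L) {
    # dense comb across the range: exactly periodic (tuned) waveform
    t_star <- stats::median(diff(lag_ref[first]))
    tuned <- TRUE
    rep_r <- max(r_ref[first])
  } else {
    t_star <- lag_ref[first[which.max(r_ref[first])]]
    reps <- vapply(split(qual, cl), function(ix) ix[which.max(r_ref[ix])],
                   numeric(1))
    rep_r <- max(r_ref[reps])
  }
  raw <- 1 / t_star
  structure(list(pattern_rate = round(raw, 1), raw_rate = raw,
                 recurrence_time = t_star, tuned = tuned,
                 best_correlation = rep_r,
                 method = "upsampled_probe_autocorrelation"),
            class = "beat_report")
}

dominant_frequency <- function(x, fs) {
  n <- length(x)
  spec <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  spec[1] <- 0
  (which.max(spec) - 1) * fs / n
}

#' @export
print.beat_report <- function(x, ...) {
  if (!is.null(x$first_order_rate)) {
    if (x$flat)
      cat("<beat_report> flat envelope: no first-order beating\n")
    else
      cat(sprintf("<beat_report> first-order beat rate %.1f Hz (%d maxima)\n",
                  x$first_order_rate, x$n_maxima))
  } else {
    cat(sprintf(
      "<beat_report> pattern beat rate %.1f Hz (T* = %.5f s%s, r = %.4f)\n",
      x$pattern_rate, x$recurrence_time,
      if (x$tuned) ", tuned/static pattern" else "", x$best_correlation))
  }
  invisible(x)
}
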