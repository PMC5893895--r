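#' Configuration for a sliding-window recurrence scan
#'
#' Bundles the scan geometry and the recurrence parameters. The defaults are
#' the settings used for the octave-sweep analysis: 480-sample windows
#' shifted by 48 samples, embedding dimension 5, lag 3, with the threshold
#' radius set per window to 10% of that window's mean pairwise epoch
#' distance.
#'
#' @param window_length window length in samples; must allow at least two
#'   epochs, i.e. `window_length >= (m - 1) * L + 2`.
#' @param shift hop between consecutive window starts, in samples
#'   (`1 <= shift <= window_length` for the usual overlapping scan; larger
#'   shifts are allowed and simply skip samples).
#' @param m,L embedding dimension and lag (see [embed_series]).
#' @param radius_policy,radius_parameter radius rule (see [select_radius]).
#' @param radius_scope `"per_window"` recomputes the radius inside every
#'   window (scale-invariant: an amplitude envelope does not bias the
#'   percent recurrence); `"global"` derives one radius from distances
#'   pooled across windows (deterministic stride subsample of ~1000
#'   below-diagonal distances per window) and applies it everywhere.
#' @return A list of class `rqe_config`.
#' @export
rqe_config <- function(window_length = 480, shift = 48, m = 5, L = 3,
                       radius_policy = "fraction_of_mean_distance",
                       radius_parameter = 0.1,
                       radius_scope = c("per_window", "global")) {
  radius_scope <- match.arg(radius_scope)
  if (window_length < (m - 1) * L + 2)
    stop("window_length ", window_length, " is too short for m=", m,
         ", L=", L, " (needs at least ", (m - 1) * L + 2, " samples)")
  if (shift < 1) stop("shift must be >= 1")
  structure(list(window_length = window_length, shift = shift, m = m, L = L,
                 radius_policy = radius_policy,
                 radius_parameter = radius_parameter,
                 radius_scope = radius_scope),
            class = "rqe_config")
}

#' Mean interval ratio of a window
#'
#' Arithmetic mean of the signal's `ratio_trajectory` over the
#' `window_length` samples starting at 0-based sample `window_start`.
#'
#' @param signal a [tone_signal] carrying a `ratio_trajectory`.
#' @param window_start 0-based index of the first sample in the window.
#' @param window_length window length in samples.
#' @return The mean interval ratio (a single number).
#' @export
window_ratio <- function(signal, window_start, window_length) {
  if (is.null(signal$ratio_trajectory))
    stop("signal carries no ratio_trajectory")
  n <- length(signal$samples)
  if (window_start < 0 || window_start + window_length > n)
    stop("window [", window_start, ", ", window_start + window_length,
         ") is out of range for a signal of length ", n)
  mean(signal$ratio_trajectory[(window_start + 1):(window_start + window_length)])
}

#' Sliding-window recurrence scan (RQE)
#'
#' Scans the signal with windows starting at samples 0, `shift`,
#' `2 * shift`, ... (0-based) as long as a full window fits; a trailing
#' partial window is discarded. Each window is embedded, its epoch distance
#' matrix thresholded under the configured radius rule, and the percent
#' recurrence recorded together with the window's mean interval ratio.
#'
#' @param signal a [tone_signal] with a `ratio_trajectory` (see
#'   [glissando_mix]).
#' @param config an [rqe_config].
#' @return A data frame of class `rqe_profile` with columns `window_start`
#'   (0-based sample), `ratio`, `percent_recurrence`, plus attributes
#'   `config` and `radius` (the vector of per-window radii actually used).
#' @examples
#' \donttest{
#' g <- glissando_mix()
#' prof <- rqe(g)
#' nrow(prof)  # 991 windows
#' }
#' @export
rqe <- function(signal, config = rqe_config()) {
  if (!inherits(signal, "tone_signal")) stop("`signal` must be a tone_signal")
  if (is.null(signal$ratio_trajectory))
    stop("signal carries no ratio_trajectory; rqe() needs one to map windows ",
         "onto the interval-ratio axis")
  n <- length(signal$samples)
  W <- config$window_length
  if (n < W)
    stop("signal (", n, " samples) is shorter than one window (", W, ")")
  starts <- seq(0L, n - W, by = config$shift)
  windows <- lapply(starts, function(s)
    signal$samples[(s + 1):(s + W)])
  dists <- lapply(windows, function(w) {
    E <- embed_series(w, config$m, config$L)
    epoch_distances(E)
  })
  if (config$radius_scope == "global") {
    pooled <- unlist(lapply(dists, function(D) {
      d <- lower_distances(D)
      step <- max(1L, length(d) %/% 1000L)
      d[seq(1L, length(d), by = step)]
    }))
    r_global <- switch(config$radius_policy,
      fraction_of_mean_distance = config$radius_parameter * mean(pooled),
      gaussian_percentile = mean(pooled) -
        stats::qnorm(1 - config$radius_parameter) *
        sqrt(mean((pooled - mean(pooled))^2)),
      empirical_percentile =
        unname(stats::quantile(pooled, config$radius_parameter, type = 7)),
      absolute = config$radius_parameter,
      stop("unknown radius policy: ", config$radius_policy))
    radii <- rep(r_global, length(dists))
  } else {
    radii <- vapply(dists, select_radius, numeric(1),
                    policy = config$radius_policy,
                    parameter = config$radius_parameter)
  }
  percent <- vapply(seq_along(dists), function(i)
    recurrence(dists[[i]], radii[i])$percent_recurrence, numeric(1))
  ratio <- vapply(starts, window_ratio, numeric(1),
                  signal = signal, window_length = W)
  out <- data.frame(window_start = starts, ratio = ratio,
                    percent_recurrence = percent)
  attr(out, "config") <- config
  attr(out, "radius") <- radii
  class(out) <- c("rqe_profile", "data.frame")
  out
}

#' Saturating radius for a reference window
#'
#' Calibration helper: returns an absolute radius slightly above the largest
#' pairwise epoch distance in the window whose mean interval ratio is
#' closest to `target_ratio`. Used as a global absolute radius, it makes the
#' reference (by default unison) window report exactly 100% recurrence,
#' anchoring the profile the way the original windowed analyses were scaled.
#'
#' @inheritParams rqe
#' @param target_ratio interval ratio of the anchor window (default 1,
#'   the unison).
#' @return An absolute radius (single number).
#' @export
calibrate_radius <- function(signal, config = rqe_config(), target_ratio = 1) {
  if (is.null(signal$ratio_trajectory))
    stop("signal carries no ratio_trajectory")
  n <- length(signal$samples)
  W <- config$window_length
  starts <- seq(0L, n - W, by = config$shift)
  ratios <- vapply(starts, window_ratio, numeric(1),
                   signal = signal, window_length = W)
  s <- starts[which.min(abs(ratios - target_ratio))]
  E <- embed_series(signal$samples[(s + 1):(s + W)], config$m, config$L)
  D <- epoch_distances(E)
  max(D) * (1 + 1e-9)
}

#' @export
print.rqe_profile <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<rqe_profile> %d windows (W=%d, shift=%d, m=%d, L=%d, %s)\n",
              nrow(x), cfg$window_length, cfg$shift, cfg$m, cfg$L,
              cfg$radius_scope))
  cat(sprintf("  ratio %.4f .. %.4f, percent recurrence %.3g .. %.3g\n",
              min(x$ratio), max(x$ratio),
              min(x$percent_recurrence), max(x$percent_recurrence)))
  invisible(x)
}

#' @export
plot.rqe_profile <- function(x, type = "l",
                             xlab = "interval ratio",
                             ylab = "percent recurrence", ...) {
  graphics::plot(x$ratio, x$percent_recurrence, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Write an RQE profile as TSV
#'
#' Columns `window_start`, `ratio`, `percent_recurrence`.
#'
#' @param profile an `rqe_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
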