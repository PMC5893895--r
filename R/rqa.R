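#' Time-delay embedding of a scalar series
#'
#' Builds the delay-embedded trajectory matrix: epoch (row) `i` is
#' `(x[i], x[i+L], ..., x[i+(m-1)*L])`, giving `N - (m-1)*L` overlapping
#' epochs from a series of length `N`.
#'
#' @param series numeric vector, or a [tone_signal] (its samples are used).
#' @param m embedding dimension (>= 1).
#' @param L lag between embedded coordinates, in samples (>= 1).
#' @return An object of class `rqa_embedding`: a list with `matrix` (epochs
#'   in rows, named `ep1...epN`), `m`, `L`, `source_length`.
#' @examples
#' E <- embed_series(c(7, 8, 10, 15, 6, 7, 9, 11, 10, 8), m = 3, L = 1)
#' nrow(E$matrix)  # 8 epochs
#' @export
embed_series <- function(series, m, L = 1) {
  if (inherits(series, "tone_signal")) series <- series$samples
  if (m < 1 || m != round(m)) stop("embedding dimension m must be a positive integer")
  if (L < 1 || L != round(L)) stop("lag L must be a positive integer")
  n <- length(series)
  need <- (m - 1) * L + 1
  if (n < need)
    stop("series too short for embedding: length ", n,
         " but m=", m, ", L=", L, " requires at least ", need, " samples")
  n_e <- n - (m - 1) * L
  idx <- outer(seq_len(n_e) - 1L, seq(0L, (m - 1L) * L, by = L), "+") + 1L
  mat <- matrix(series[idx], nrow = n_e, ncol = m)
  rownames(mat) <- paste0("ep", seq_len(n_e))
  structure(list(matrix = mat, m = m, L = L, source_length = n),
            class = "rqa_embedding")
}

#' @export
print.rqa_embedding <- function(x, ...) {
  cat(sprintf("<rqa_embedding> %d epochs, m = %d, L = %d (series length %d)\n",
              nrow(x$matrix), x$m, x$L, x$source_length))
  invisible(x)
}

#' Euclidean distance matrix between epochs
#'
#' Full symmetric matrix of Euclidean distances between the rows of an
#' embedding, zero on the diagonal, with epoch labels `ep1...epN`.
#'
#' @param embedding an [rqa_embedding] (or a plain numeric matrix of epochs).
#' @return A symmetric numeric matrix of class `epoch_distances`.
#' @export
epoch_distances <- function(embedding) {
  mat <- if (inherits(embedding, "rqa_embedding")) embedding$matrix else embedding
  if (nrow(mat) < 2L) stop("need at least 2 epochs to compute distances")
  d <- as.matrix(stats::dist(mat, method = "euclidean"))
  labs <- paste0("ep", seq_len(nrow(mat)))
  dimnames(d) <- list(labs, labs)
  class(d) <- c("epoch_distances", class(d))
  d
}

lower_distances <- function(D) D[lower.tri(D)]

#' Recurrence radius selection policies
#'
#' Turns a distance matrix into a threshold radius under one of four
#' policies, all computed from the strictly-below-diagonal distances:
#'
#' * `fraction_of_mean_distance`: `parameter * mean(d)` — the common
#'   "5–10% of the average pairwise distance" rule (`parameter` = 0.05–0.1).
#' * `gaussian_percentile`: `mean(d) - qnorm(1 - parameter) * sd_pop(d)`,
#'   the radius below which a Gaussian fit leaves `parameter` of the mass
#'   (one-sided; `parameter` = 0.05 uses z = 1.6449). Population SD
#'   (divisor n). May be non-positive for small `parameter` on tight
#'   distributions; `recurrence()` rejects non-positive radii.
#' * `empirical_percentile`: the `parameter`-quantile of the distances
#'   (linear interpolation, `stats::quantile` type 7).
#' * `absolute`: `parameter` itself.
#'
#' @param D an [epoch_distances] matrix.
#' @param policy one of the four policy names above.
#' @param parameter policy parameter (fraction, tail probability, quantile
#'   level, or the radius itself; must be positive, and in \[0, 1\] for the
#'   percentile policies).
#' @return The radius (a single number).
#' @export
select_radius <- function(D,
                          policy = c("fraction_of_mean_distance",
                                     "gaussian_percentile",
                                     "empirical_percentile", "absolute"),
                          parameter) {
  policy <- match.arg(policy)
  if (!is.numeric(parameter) || length(parameter) != 1L)
    stop("`parameter` must be a single number")
  d <- lower_distances(D)
  switch(policy,
    fraction_of_mean_distance = {
      if (parameter <= 0) stop("fraction must be positive")
      parameter * mean(d)
    },
    gaussian_percentile = {
      if (parameter <= 0 || parameter >= 1)
        stop("gaussian tail probability must be in (0, 1)")
      sd_pop <- sqrt(mean((d - mean(d))^2))
      mean(d) - stats::qnorm(1 - parameter) * sd_pop
    },
    empirical_percentile = {
      if (parameter < 0 || parameter > 1)
        stop("empirical quantile level must be in [0, 1]")
      unname(stats::quantile(d, parameter, type = 7))
    },
    absolute = {
      if (parameter <= 0) stop("absolute radius must be positive")
      parameter
    })
}

#' Recurrence plot and percent recurrence
#'
#' Thresholds a distance matrix at `radius`: epochs i and j (i != j) are
#' recurrent iff `D[i, j] < radius` (strict; ties at exactly the radius are
#' non-recurrent). Each unordered pair is counted once, so the maximum count
#' is `N_e * (N_e - 1) / 2` for `N_e` epochs.
#'
#' @param D an [epoch_distances] matrix.
#' @param radius threshold radius (> 0).
#' @return An object of class `rqa_result`: list with `radius`,
#'   `recurrence_count`, `pair_count`, `rate` (count / pairs),
#'   `percent_recurrence` (100 * rate) and `recurrence_plot` (binary
#'   symmetric 0/1 matrix, zero diagonal).
#' @export
recurrence <- function(D, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a single positive number (got ",
         format(radius), ")")
  n <- nrow(D)
  rp <- (D < radius) * 1L
  diag(rp) <- 0L
  count <- sum(rp[lower.tri(rp)])
  pairs <- n * (n - 1) / 2
  structure(
    list(radius = radius, recurrence_count = count, pair_count = pairs,
         rate = count / pairs, percent_recurrence = 100 * count / pairs,
         recurrence_plot = rp),
    class = "rqa_result")
}

#' @export
print.rqa_result <- function(x, ...) {
  cat(sprintf(paste0("<rqa_result> %d recurrent pairs / %d (rate %.4g, ",
                     "%.4g%%), radius %.6g\n"),
              x$recurrence_count, x$pair_count, x$rate,
              x$percent_recurrence, x$radius))
  invisible(x)
}

#' @export
plot.rqa_result <- function(x, ...) {
  n <- nrow(x$recurrence_plot)
  graphics::image(seq_len(n), seq_len(n), t(x$recurrence_plot),
                  col = c("white", "black"), xlab = "epoch", ylab = "epoch",
                  ...)
  invisible(x)
}

#' One-shot recurrence quantification
#'
#' Convenience wrapper: embed, compute distances, select the radius, and
#' threshold, returning the [recurrence] result with the embedding and
#' distance matrix attached.
#'
#' @inheritParams embed_series
#' @inheritParams select_radius
#' @param radius_policy,radius_parameter passed to [select_radius].
#' @return An `rqa_result` with extra elements `embedding` and `distances`.
#' @export
rqa <- function(series, m = 5, L = 3,
                radius_policy = "fraction_of_mean_distance",
                radius_parameter = 0.1) {
  E <- embed_series(series, m, L)
  D <- epoch_distances(E)
  r <- select_radius(D, radius_policy, radius_parameter)
  out <- recurrence(D, r)
  out$embedding <- E
  out$distances <- D
  out
}

#' Write a recurrence plot or distance matrix as plain text
#'
#' The recurrence plot is emitted as a 0/1 matrix (space-separated); the
#' distance matrix as a TSV with 1-based epoch labels `ep1...epN` on both
#' axes.
#'
#' @param x an `rqa_result` or `epoch_distances` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rqa_text <- function(x, path) {
  if (inherits(x, "rqa_result")) {
    utils::write.table(x$recurrence_plot, path, sep = " ",
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(format(unclass(x), digits = 7), path, sep = "\t",
                       quote = FALSE, row.names = TRUE, col.names = NA)
  }
  invisible(path)
}

# ---- mutual information lag selection --------------------------------------

#' First minimum of average mutual information
#'
#' Histogram estimate of the mutual information `I(x_t; x_{t+lag})` over
#' lags `1..max_lag`, returning the smallest lag at which I is a strict
#' local minimum — the standard heuristic for choosing the embedding lag.
#'
#' The joint density is estimated on an `n_bins x n_bins` equal-width grid
#' over the series range. A series whose lag-1 information does not exceed
#' a noise floor of `2 * (n_bins - 1)^2 / (2 * N)` nats (twice the
#' first-order positive bias of the plug-in estimator) is treated as
#' structureless: the search is abandoned and `max_lag` returned with
#' `found = FALSE`. The same fallback applies when no local minimum exists
#' within `max_lag`. An optional Miller–Madow bias correction is available
#' but off by default.
#'
#' @inheritParams embed_series
#' @param max_lag largest lag to examine; must be below `N / 2`.
#' @param n_bins number of histogram bins per axis (default 16). A warning
#'   is issued when `N < n_bins^2` (unreliable estimator).
#' @param miller_madow logical; apply the Miller–Madow entropy correction.
#' @return A list of class `ami_lag`: `lag`, `found` (logical; `FALSE`
#'   means the fallback `max_lag` was returned), `mi` (numeric vector of
#'   I at lags `1..max_lag`, in nats).
#' @export
ami_first_minimum <- function(series, max_lag = 20, n_bins = 16,
                              miller_madow = FALSE) {
  if (inherits(series, "tone_signal")) series <- series$samples
  n <- length(series)
  if (max_lag < 1) stop("max_lag must be >= 1")
  if (max_lag >= n / 2) stop("max_lag must be below half the series length")
  rng <- range(series)
  if (rng[1] == rng[2])
    stop("mutual information is undefined for a constant series")
  if (n < n_bins^2)
    warning("series length ", n, " is below n_bins^2 = ", n_bins^2,
            "; the histogram MI estimate is unreliable")
  # equal-width bins over the range; top edge inclusive
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(series, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mi <- vapply(seq_len(max_lag), function(l) {
    a <- bin[seq_len(n - l)]
    b <- bin[(1 + l):n]
    joint <- tabulate(a + n_bins * (b - 1L), nbins = n_bins^2)
    m <- length(a)
    p <- joint / m
    pa <- tabulate(a, nbins = n_bins) / m
    pb <- tabulate(b, nbins = n_bins) / m
    nz <- p > 0
    pp <- outer(pa, pb)[nz]
    val <- sum(p[nz] * log(p[nz] / pp))
    if (miller_madow) {
      # H_mm = H + (K-1)/(2n) per entropy; MI = Ha + Hb - Hab
      ka <- sum(pa > 0); kb <- sum(pb > 0); kab <- sum(nz)
      val <- val + (ka - 1) / (2 * m) + (kb - 1) / (2 * m) -
        (kab - 1) / (2 * m)
    }
    val
  }, numeric(1))
  floor_mi <- (n_bins - 1)^2 / n   # 2x the first-order plug-in bias
  found <- FALSE
  lag <- max_lag
  if (mi[1] > floor_mi && max_lag >= 2) {
    for (l in seq_len(max_lag)) {
      left <- if (l == 1) Inf else mi[l - 1]
      right <- if (l == max_lag) Inf else mi[l + 1]
      if (mi[l] < left && mi[l] < right && l < max_lag) {
        lag <- l
        found <- TRUE
        break
      }
    }
  }
  structure(list(lag = lag, found = found, mi = mi), class = "ami_lag")
}

#' @export
print.ami_lag <- function(x, ...) {
  cat(sprintf("<ami_lag> first MI minimum at lag %d%s\n", x$lag,
              if (x$found) "" else " (fallback: no clear minimum found)"))
  invisible(x)
}
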