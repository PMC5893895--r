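#' Detect recurrence peaks in an RQE profile
#'
#' Local maxima of percent recurrence along the ratio axis by strict
#' neighbor comparison (a flat-topped run of equal values counts once, at
#' its lower-ratio end), filtered by topographic prominence and by a
#' minimum separation on the ratio axis (when two peaks fall closer than
#' `min_separation`, the lower one is dropped; equal heights keep the lower
#' ratio). Each surviving peak is matched to the closest small-denominator
#' rational and, through it, to the interval catalog.
#'
#' @param profile an `rqe_profile` (or any data frame with `ratio` and
#'   `percent_recurrence` columns, ordered or orderable by ratio).
#' @param min_prominence minimum topographic prominence, in percent
#'   recurrence units (default 1).
#' @param min_separation minimum distance between retained peaks on the
#'   ratio axis (default 0.01).
#' @param max_denominator passed to [match_rational].
#' @param match_tolerance maximum |ratio - num/den| for a rational match to
#'   be accepted (default 0.005); unmatched peaks keep `NA` in the rational
#'   columns.
#' @return A data frame of class `peak_set`, sorted by descending percent
#'   recurrence: columns `ratio`, `percent_recurrence`, `prominence`,
#'   `num`, `den`, `rational` (num/den), `label`, `name`.
#' @export
detect_peaks <- function(profile, min_prominence = 1, min_separation = 0.01,
                         max_denominator = 11, match_tolerance = 0.005) {
  if (nrow(profile) == 0L) stop("empty profile")
  ord <- order(profile$ratio)
  x <- profile$ratio[ord]
  y <- profile$percent_recurrence[ord]
  n <- length(y)
  # collapse plateaus: strict local maxima against previous/next distinct value
  is_peak <- logical(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    left_ok <- i > 1L && y[i - 1L] < y[i]
    right_ok <- j < n && y[j + 1L] < y[i]
    if (left_ok && right_ok) is_peak[i] <- TRUE
    i <- j + 1L
  }
  idx <- which(is_peak)
  if (length(idx) == 0L) {
    out <- data.frame(ratio = numeric(0), percent_recurrence = numeric(0),
                      prominence = numeric(0), num = integer(0),
                      den = integer(0), rational = numeric(0),
                      label = character(0), name = character(0))
    class(out) <- c("peak_set", "data.frame")
    return(out)
  }
  prominence <- vapply(idx, function(p) {
    h <- y[p]
    # walk left/right to the nearest strictly higher sample (or the border);
    # the key saddle is the higher of the two intervening minima
    lmin <- h
    k <- p
    while (k > 1L) {
      k <- k - 1L
      if (y[k] > h) break
      if (y[k] < lmin) lmin <- y[k]
    }
    rmin <- h
    k <- p
    while (k < n) {
      k <- k + 1L
      if (y[k] > h) break
      if (y[k] < rmin) rmin <- y[k]
    }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prominence >= min_prominence
  idx <- idx[keep]
  prominence <- prominence[keep]
  # separation filter: greedily accept in order of height (ties: lower ratio)
  ord2 <- order(-y[idx], x[idx])
  accepted <- integer(0)
  acc_pos <- numeric(0)
  for (k in ord2) {
    if (all(abs(x[idx[k]] - acc_pos) >= min_separation)) {
      accepted <- c(accepted, k)
      acc_pos <- c(acc_pos, x[idx[k]])
    }
  }
  idx <- idx[accepted]
  prominence <- prominence[accepted]
  m <- lapply(x[idx], match_rational, max_denominator = max_denominator)
  num <- vapply(m, `[[`, numeric(1), "num")
  den <- vapply(m, `[[`, numeric(1), "den")
  err <- vapply(m, `[[`, numeric(1), "error")
  bad <- err > match_tolerance
  num[bad] <- NA; den[bad] <- NA
  cat_df <- interval_catalog()
  key <- paste(num, den)
  cat_key <- paste(cat_df$num, cat_df$den)
  hit <- match(key, cat_key)
  out <- data.frame(ratio = x[idx], percent_recurrence = y[idx],
                    prominence = prominence, num = num, den = den,
                    rational = num / den,
                    label = ifelse(is.na(hit), NA_character_,
                                   cat_df$label[hit]),
                    name = ifelse(is.na(hit), NA_character_,
                                  cat_df$name[hit]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent_recurrence, out$ratio), ]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Rank detected peaks against the reference consonance order
#'
#' Matches each interval of a reference label list (default the classical
#' ten-consonance order, see [consonance_reference]) to a detected peak by
#' its rational, orders the matched labels by descending peak recurrence,
#' and reports Spearman's rank correlation between the observed ordering
#' and the reference.
#'
#' @param peaks a `peak_set` from [detect_peaks].
#' @param reference character vector of catalog labels, most consonant
#'   first.
#' @return A list of class `consonance_ranking`: `labels` (matched labels in
#'   descending recurrence order), `rho` (Spearman correlation), `matched`
#'   (data frame with label, reference position, peak ratio and recurrence),
#'   `unmatched` (reference labels with no detected peak).
#' @export
rank_consonance <- function(peaks, reference = consonance_reference()) {
  cat_df <- interval_catalog()
  ref <- cat_df[match(reference, cat_df$label), ]
  if (anyNA(ref$num)) stop("unknown reference label(s): ",
                           paste(reference[is.na(ref$num)], collapse = ", "))
  key <- paste(peaks$num, peaks$den)
  rows <- match(paste(ref$num, ref$den), key)
  matched <- !is.na(rows)
  if (sum(matched) < 2L)
    stop("fewer than 2 reference intervals matched a detected peak")
  df <- data.frame(label = reference[matched],
                   reference_position = which(matched),
                   ratio = peaks$ratio[rows[matched]],
                   percent_recurrence = peaks$percent_recurrence[rows[matched]],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$percent_recurrence), ]
  rownames(df) <- NULL
  rho <- stats::cor(df$reference_position, rank(-df$percent_recurrence),
                    method = "spearman")
  structure(list(labels = df$label, rho = rho, matched = df,
                 unmatched = reference[!matched]),
            class = "consonance_ranking")
}

#' @export
print.consonance_ranking <- function(x, ...) {
  cat("<consonance_ranking> ", paste(x$labels, collapse = " > "),
      sprintf("\n  Spearman rho vs reference: %.3f\n", x$rho))
  if (length(x$unmatched))
    cat("  unmatched:", paste(x$unmatched, collapse = ", "), "\n")
  invisible(x)
}

#' Correlate peak recurrence with Frova's index
#'
#' Pearson correlation (and the ordinary least squares line, recurrence as
#' response) between the percent recurrence of matched peaks and Frova's
#' index `(m + n) / (m * n)` of their rationals, over the reference interval
#' set.
#'
#' @inheritParams rank_consonance
#' @return A list of class `frova_fit`: `r` (Pearson correlation), `slope`,
#'   `intercept`, `n`, `underdetermined` (TRUE when only two points), and
#'   `data` (the matched label/index/recurrence table).
#' @export
frova_correlation <- function(peaks, reference = consonance_reference()) {
  cat_df <- interval_catalog()
  ref <- cat_df[match(reference, cat_df$label), ]
  key <- paste(peaks$num, peaks$den)
  rows <- match(paste(ref$num, ref$den), key)
  matched <- !is.na(rows)
  if (sum(matched) < 2L)
    stop("fewer than 2 reference intervals matched a detected peak")
  fi <- frova_index(ref$num[matched], ref$den[matched])
  pr <- peaks$percent_recurrence[rows[matched]]
  if (stats::sd(fi) == 0 || stats::sd(pr) == 0)
    stop("degenerate variance: cannot correlate")
  fit <- stats::lm(pr ~ fi)
  structure(list(r = stats::cor(fi, pr),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = sum(matched), underdetermined = sum(matched) == 2L,
                 data = data.frame(label = reference[matched],
                                   frova = fi, percent_recurrence = pr,
                                   stringsAsFactors = FALSE)),
            class = "frova_fit")
}

#' @export
print.frova_fit <- function(x, ...) {
  cat(sprintf("<frova_fit> Pearson r = %.4f over %d intervals%s\n", x$r, x$n,
              if (x$underdetermined) " (underdetermined: 2 points)" else ""))
  cat(sprintf("  recurrence = %.3f + %.3f * frova\n", x$intercept, x$slope))
  invisible(x)
}

#' Cumulative recurrence staircase
#'
#' Running sum of percent recurrence along ascending interval ratio,
#' normalized by the grand total, so the curve rises from ~0 to exactly 1.
#' Flat stretches correspond to dissonant (low-recurrence) regions and the
#' large vertical jumps to the dominant consonances, mirroring the
#' structure of a mode-locking staircase.
#'
#' @param profile an `rqe_profile`.
#' @return A data frame of class `staircase_curve` with columns `x` (ratio)
#'   and `y` (cumulative recurrence in \[0, 1\]).
#' @export
cumulative_recurrence <- function(profile) {
  if (nrow(profile) == 0L) stop("empty profile")
  ord <- order(profile$ratio)
  y <- profile$percent_recurrence[ord]
  if (all(y == 0)) stop("all-zero profile: cumulative recurrence undefined")
  out <- data.frame(x = profile$ratio[ord], y = cumsum(y) / sum(y))
  class(out) <- c("staircase_curve", "data.frame")
  out
}

#' @export
plot.staircase_curve <- function(x, type = "s", xlab = "x", ylab = "y", ...) {
  graphics::plot(x$x, x$y, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Write peaks or staircases as TSV
#' @param x a `peak_set` or `staircase_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
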