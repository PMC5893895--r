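# Shared fixtures and independent oracles.

# the 10-value worked-example series
worked_series <- function() c(7, 8, 10, 15, 6, 7, 9, 11, 10, 8)

# its published distance matrix, below-diagonal rows ep2..ep8
worked_lower_tri <- function() {
  list(
    c(5.477226),
    c(8.602325, 10.48809),
    c(8.774964, 11.35782, 10.34408),
    c(1.732051, 7, 9.433981, 9.273618),
    c(1.41421, 4.242641, 8.3666, 9.433981, 3),
    c(3.605551, 5.196152, 5.744563, 8.3666, 5.09902, 3),
    c(4.898979, 7.615773, 5.477226, 5.744563, 5.91608, 5.09902, 3))
}

# independent O(N^2) oracle: percent recurrence by explicit double loop
naive_percent_recurrence <- function(x, m, L, radius) {
  n_e <- length(x) - (m - 1) * L
  count <- 0
  for (i in seq_len(n_e - 1)) {
    for (j in (i + 1):n_e) {
      vi <- x[i + (0:(m - 1)) * L]
      vj <- x[j + (0:(m - 1)) * L]
      if (sqrt(sum((vi - vj)^2)) < radius) count <- count + 1
    }
  }
  100 * count / (n_e * (n_e - 1) / 2)
}

# independent histogram mutual-information curve (different code path from
# the package: table() over cut() factors)
naive_mi_curve <- function(x, max_lag, n_bins = 16) {
  br <- seq(min(x), max(x), length.out = n_bins + 1)
  f <- cut(x, breaks = br, include.lowest = TRUE)
  sapply(seq_len(max_lag), function(l) {
    n <- length(x) - l
    tab <- table(f[1:n], f[(1 + l):(n + l)])
    p <- tab / n
    px <- rowSums(p); py <- colSums(p)
    keep <- p > 0
    sum((p * log(p / outer(px, py)))[keep])
  })
}

# synthetic RQE profile from explicit ratio/percent vectors
fake_profile <- function(ratio, percent) {
  out <- data.frame(window_start = seq_along(ratio) - 1L, ratio = ratio,
                    percent_recurrence = percent)
  class(out) <- c("rqe_profile", "data.frame")
  out
}

# peak_set built directly from catalog labels and chosen recurrence values
fake_peaks <- function(labels, percents) {
  cat_df <- interval_catalog()
  rows <- match(labels, cat_df$label)
  out <- data.frame(ratio = cat_df$num[rows] / cat_df$den[rows],
                    percent_recurrence = percents,
                    prominence = percents,
                    num = cat_df$num[rows], den = cat_df$den[rows],
                    rational = cat_df$num[rows] / cat_df$den[rows],
                    label = labels, name = cat_df$name[rows],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent_recurrence), ]
  class(out) <- c("peak_set", "data.frame")
  out
}
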