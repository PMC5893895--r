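test_that("match_rational recovers catalog rationals from peak positions", {
  m <- match_rational(1.5003)
  expect_equal(c(m$num, m$den), c(3, 2))
  m2 <- match_rational(1.6671)
  expect_equal(c(m2$num, m2$den), c(5, 3))
  expect_equal(match_rational(1.0)$den, 1)
  expect_equal(match_rational(1.0)$num, 1)
  # exact rationals are fixed points for every catalog row
  cat_df <- interval_catalog()
  for (i in seq_len(nrow(cat_df))) {
    m <- match_rational(cat_df$num[i] / cat_df$den[i])
    expect_equal(c(m$num, m$den), c(cat_df$num[i], cat_df$den[i]))
  }
  # ties go to the smaller denominator
  expect_equal(match_rational(1.25, max_denominator = 8)$den, 4)
  expect_error(match_rational(-1), "positive")
})

test_that("Frova's index follows (m+n)/(m*n) and its order", {
  expect_equal(frova_index(1, 1), 2)
  expect_equal(frova_index(2, 1), 1.5)
  expect_equal(frova_index(3, 2), 5 / 6)
  expect_equal(frova_index(3, 2), frova_index(2, 3))  # symmetry
  prefix <- list(c(1, 1), c(2, 1), c(3, 2), c(4, 3), c(5, 3))
  vals <- vapply(prefix, function(p) frova_index(p[1], p[2]), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(frova_index(4, 2), "lowest terms")
  expect_error(frova_index(3, 0), "non-zero")
})

test_that("interval catalog is reduced and spans the octave", {
  cat_df <- interval_catalog()
  expect_equal(nrow(cat_df), 31)
  g <- mapply(function(a, b) recurtone:::gcd_int(a, b),
              cat_df$num, cat_df$den)
  expect_true(all(g == 1))
  expect_true(all(cat_df$num / cat_df$den >= 1 - 1e-9))
  expect_true(all(cat_df$num / cat_df$den <= 2 + 1e-9))
  expect_true(any(cat_df$caveat))   # the published 1.8567 / 15-8 quirk
  expect_equal(consonance_reference()[1:4], c("U", "P8", "P5", "P4"))
})

test_that("peak detection honors prominence, separation and tie rules", {
  # a clean triangular peak
  p <- fake_profile(seq(1, 2, by = 0.01),
                    c(seq(0, 10, length.out = 51),
                      seq(9.8, 0, length.out = 50)))
  pk <- detect_peaks(p, min_prominence = 1, min_separation = 0.01)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$ratio, 1.5)
  expect_equal(c(pk$num, pk$den), c(3, 2))
  # monotone profile: no interior peaks
  mono <- fake_profile(seq(1, 2, by = 0.01), seq(0, 50, length.out = 101))
  expect_equal(nrow(detect_peaks(mono)), 0)
  # two equal adjacent maxima: one peak, at the lower ratio
  y <- c(0, 1, 5, 5, 1, 0)
  tie <- fake_profile(seq(1, 1.5, length.out = 6), y)
  pk2 <- detect_peaks(tie, min_prominence = 1, min_separation = 0.01)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$ratio, 1.2)
  # low-prominence shoulder bumps are filtered
  y3 <- c(0, 10, 9, 9.5, 8, 0, 0)
  p3 <- fake_profile(seq(1, 1.6, length.out = 7), y3)
  pk3 <- detect_peaks(p3, min_prominence = 1, min_separation = 0.001)
  expect_equal(nrow(pk3), 1)
  expect_equal(pk3$percent_recurrence, 10)
  # close peaks merged by the separation rule, keeping the higher
  y4 <- c(0, 8, 0.5, 6, 0)
  p4 <- fake_profile(c(1, 1.002, 1.004, 1.006, 1.008), y4)
  pk4 <- detect_peaks(p4, min_prominence = 1, min_separation = 0.01)
  expect_equal(nrow(pk4), 1)
  expect_equal(pk4$percent_recurrence, 8)
  expect_error(detect_peaks(fake_profile(numeric(0), numeric(0))), "empty")
})

test_that("consonance ranking reports Spearman rho against the reference", {
  ref <- consonance_reference()
  rk <- rank_consonance(fake_peaks(ref, seq(100, 10, length.out = 10)))
  expect_equal(rk$labels, ref)
  expect_equal(rk$rho, 1)
  rk2 <- rank_consonance(fake_peaks(ref, seq(10, 100, length.out = 10)))
  expect_equal(rk2$rho, -1)
  expect_error(rank_consonance(fake_peaks("U", 100)), "fewer than 2")
  expect_error(rank_consonance(fake_peaks(ref, 1:10),
                               reference = c("U", "XX")), "unknown")
})

test_that("Frova correlation is exact on constructed data", {
  ref <- consonance_reference()
  cat_df <- interval_catalog()
  rows <- match(ref, cat_df$label)
  fi <- frova_index(cat_df$num[rows], cat_df$den[rows])
  # perfectly linear response gives r = 1 and the planted coefficients
  fv <- frova_correlation(fake_peaks(ref, 3 + 40 * fi))
  expect_equal(fv$r, 1)
  expect_equal(fv$slope, 40)
  expect_equal(fv$intercept, 3)
  expect_false(fv$underdetermined)
  # two points: |r| = 1 but flagged underdetermined
  fv2 <- frova_correlation(fake_peaks(c("U", "P5"), c(50, 10)))
  expect_true(fv2$underdetermined)
  expect_equal(abs(fv2$r), 1)
  expect_error(frova_correlation(fake_peaks(c("U", "P5"), c(10, 10))),
               "degenerate")
})

test_that("cumulative recurrence is a normalized non-decreasing staircase", {
  p <- fake_profile(seq(1, 2, by = 0.1), c(1, 5, 2, 8, 1, 1, 9, 2, 1, 4, 3))
  cc <- cumulative_recurrence(p)
  expect_equal(cc$y[length(cc$y)], 1)
  expect_true(all(diff(cc$y) >= 0))
  # flat profile: uniform mass, equal increments
  flat <- cumulative_recurrence(fake_profile(seq(1, 2, by = 0.1),
                                             rep(3, 11)))
  expect_equal(diff(flat$y), rep(1 / 11, 10))
  expect_error(cumulative_recurrence(fake_profile(1:3, c(0, 0, 0))),
               "all-zero")
})
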