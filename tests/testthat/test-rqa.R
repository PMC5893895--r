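test_that("delay embedding reproduces the worked-example matrix", {
  E <- embed_series(worked_series(), m = 3, L = 1)
  expect_equal(nrow(E$matrix), 8)
  expect_equal(unname(E$matrix[1, ]), c(7, 8, 10))
  expect_equal(unname(E$matrix[2, ]), c(8, 10, 15))
  expect_equal(unname(E$matrix[8, ]), c(11, 10, 8))
  expect_equal(rownames(E$matrix)[1], "ep1")
  # m = 1 is the identity embedding
  E1 <- embed_series(worked_series(), m = 1)
  expect_equal(as.numeric(E1$matrix), worked_series())
  # length bound: N = 10, m = 5, L = 3 needs 13 samples
  expect_error(embed_series(worked_series(), m = 5, L = 3), "13")
  expect_error(embed_series(1:10, m = 0), "positive integer")
})

test_that("epoch distances are Euclidean, symmetric, zero-diagonal", {
  D <- epoch_distances(embed_series(worked_series(), 3, 1))
  expect_equal(unname(diag(D)), rep(0, 8))
  expect_equal(unname(D), unname(t(D)))
  expect_equal(D["ep1", "ep5"], sqrt(3), tolerance = 1e-7)
  expect_equal(D["ep1", "ep6"], sqrt(2), tolerance = 1e-7)
  expect_equal(D["ep1", "ep2"], sqrt(30), tolerance = 1e-7)
  expect_error(epoch_distances(embed_series(1:3, 3, 1)), "at least 2")
})

test_that("radius policies implement their stated rules", {
  D <- epoch_distances(embed_series(worked_series(), 3, 1))
  d <- D[lower.tri(D)]
  expect_equal(select_radius(D, "fraction_of_mean_distance", 0.1),
               0.1 * mean(d))
  expect_equal(select_radius(D, "absolute", 1.5), 1.5)
  expect_equal(select_radius(D, "empirical_percentile", 0),
               min(d))
  sd_pop <- sqrt(mean((d - mean(d))^2))
  expect_equal(select_radius(D, "gaussian_percentile", 0.05),
               mean(d) - qnorm(0.95) * sd_pop)
  # gaussian 5% lands between the 2nd and 3rd smallest distance, giving
  # exactly the two published recurrences
  r <- select_radius(D, "gaussian_percentile", 0.05)
  expect_gt(r, 1.732051)
  expect_lt(r, 3)
  expect_equal(recurrence(D, r)$recurrence_count, 2)
  # absolute 1.5: only sqrt(2) falls below
  expect_equal(recurrence(D, 1.5)$recurrence_count, 1)
  # empirical 0%: radius equals the smallest distance, strict < gives none
  expect_equal(recurrence(D, select_radius(D, "empirical_percentile", 0) +
                            0)$recurrence_count,
               0, ignore_attr = TRUE)
  expect_error(select_radius(D, "gaussian_percentile", 1.2), "in \\(0, 1\\)")
  expect_error(select_radius(D, "fraction_of_mean_distance", -1), "positive")
  expect_error(select_radius(D, "nonsense", 1))
})

test_that("recurrence counting matches the worked example", {
  D <- epoch_distances(embed_series(worked_series(), 3, 1))
  for (r in c(1.7321, 2, 2.5, 2.999)) {
    res <- recurrence(D, r)
    expect_equal(res$recurrence_count, 2)
    expect_equal(res$pair_count, 28)
    expect_equal(res$rate, 2 / 28)
    expect_equal(res$percent_recurrence, 100 * 2 / 28)
  }
  # the recurrence plot marks exactly (1,5) and (1,6)
  rp <- recurrence(D, 2)$recurrence_plot
  expect_equal(sum(rp), 4)  # symmetric pairs
  expect_equal(rp[1, 5], 1)
  expect_equal(rp[1, 6], 1)
  expect_equal(rp[5, 6], 0)
  # radius above the maximum distance saturates at 100%
  expect_equal(recurrence(D, max(D) + 1)$percent_recurrence, 100)
  expect_error(recurrence(D, 0), "positive")
})

test_that("ties at exactly the radius are non-recurrent (strict <)", {
  D <- epoch_distances(embed_series(c(0, 0, 1, 0, 0, 1), m = 1))
  # distances are exactly 0 or 1
  expect_equal(recurrence(D, 1)$recurrence_count,
               sum(D[lower.tri(D)] < 1))
  expect_lt(recurrence(D, 1)$percent_recurrence,
            recurrence(D, 1 + 1e-9)$percent_recurrence)
})

test_that("percent recurrence agrees with a naive double loop and is
           monotone in the radius", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(50)
    m <- sample(1:3, 1)
    L <- sample(1:2, 1)
    D <- epoch_distances(embed_series(x, m, L))
    radii <- sort(runif(4, 0.1, 3))
    pct <- vapply(radii, function(r) recurrence(D, r)$percent_recurrence,
                  numeric(1))
    expect_equal(pct[1], naive_percent_recurrence(x, m, L, radii[1]))
    expect_equal(pct[4], naive_percent_recurrence(x, m, L, radii[4]))
    expect_true(all(diff(pct) >= 0))
  }
})

test_that("degenerate series behave as the metric dictates", {
  # constant series: all-zero distances, 100% recurrence at any radius
  D <- epoch_distances(embed_series(rep(4, 20), 3, 2))
  expect_true(all(D == 0))
  expect_equal(recurrence(D, 1e-9)$percent_recurrence, 100)
  # integer-period signal, m = 1: distance 0 at index separation P
  x <- sin(2 * pi * (0:99) / 20)
  D2 <- epoch_distances(embed_series(x, 1))
  for (i in c(1, 7, 31)) {
    expect_equal(D2[i, i + 20], 0, tolerance = 1e-12)
    expect_equal(D2[i, i + 40], 0, tolerance = 1e-12)
  }
})

test_that("AMI first minimum sits near the quarter period of a sinusoid", {
  set.seed(42)
  x <- sin(2 * pi * (0:1999) / 20) + rnorm(2000, sd = 0.05)
  a <- ami_first_minimum(x, max_lag = 12)
  expect_true(a$found)
  expect_gte(a$lag, 4)  # quarter period is 5
  expect_lte(a$lag, 7)
  # oracle equivalence: same curve from an independent implementation
  expect_equal(a$mi, naive_mi_curve(x, 12), tolerance = 1e-10)
})

test_that("AMI flags structureless and degenerate series", {
  set.seed(7)
  wn <- rnorm(1000)
  a <- ami_first_minimum(wn, max_lag = 20)
  expect_false(a$found)
  expect_equal(a$lag, 20)
  expect_lt(max(a$mi), 0.3)  # flat, near zero
  expect_error(ami_first_minimum(rep(1, 100), 10), "constant")
  expect_error(ami_first_minimum(rnorm(100), 60), "half the series")
  expect_warning(ami_first_minimum(rnorm(100), 10), "unreliable")
})
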