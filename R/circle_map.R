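#' Iterate the sine circle map
#'
#' The standard circle map on the lift (phases accumulated without
#' reduction mod 1):
#' `theta[j+1] = theta[j] + omega + (k / (2*pi)) * sin(2*pi*theta[j])`.
#' `omega` is the bare winding number (the imposed rotation per step) and
#' `k` the coupling strength; at the critical value k = 1 the map remains
#' monotone and its mode-locked plateaus cover the whole omega axis.
#'
#' @param omega bare winding number (any real; typically in \[0, 1\]).
#' @param k coupling strength (>= 0).
#' @param theta0 initial phase (default 0.2, off the k = 1, omega = 0
#'   fixed point at 0).
#' @param n_transient burn-in iterations discarded by [winding_number].
#' @param n_iter counted iterations.
#' @return Numeric vector of length `n_transient + n_iter + 1`: the orbit
#'   on the lift, starting at `theta0`.
#' @export
circle_map_orbit <- function(omega, k = 1, theta0 = 0.2,
                             n_transient = 1000, n_iter = 10000) {
  if (k < 0) stop("k must be >= 0")
  if (n_iter < 1) stop("n_iter must be >= 1")
  n <- n_transient + n_iter
  theta <- numeric(n + 1)
  theta[1] <- theta0
  cc <- k / (2 * pi)
  th <- theta0
  for (j in seq_len(n)) {
    th <- th + omega + cc * sin(2 * pi * th)
    theta[j + 1] <- th
  }
  theta
}

#' Dressed winding number
#'
#' Long-run rotation per step of the circle map, measured on the lift after
#' discarding the transient: `w = (theta[end] - theta[after burn-in]) /
#' n_iter`. For k = 0 this equals omega exactly (up to round-off); for
#' 0 < k <= 1 the map locks onto rational w over finite omega intervals.
#'
#' @inheritParams circle_map_orbit
#' @return A list of class `winding_result`: `w`, `converged` (logical) and
#'   `residual` (absolute difference between the full-span estimate and the
#'   estimate over the last half of the counted iterations).
#' @export
winding_number <- function(omega, k = 1, theta0 = 0.2,
                           n_transient = 1000, n_iter = 10000) {
  th <- circle_map_orbit(omega, k, theta0, n_transient, n_iter)
  a <- n_transient + 1          # index of first counted phase
  b <- n_transient + n_iter + 1
  w <- (th[b] - th[a]) / n_iter
  half <- floor(n_iter / 2)
  w_half <- (th[b] - th[b - half]) / half
  residual <- abs(w - w_half)
  structure(list(w = w, converged = residual < 1e-7, residual = residual),
            class = "winding_result")
}

#' @export
print.winding_result <- function(x, ...) {
  cat(sprintf("<winding_result> w = %.9f (residual %.2e%s)\n", x$w,
              x$residual, if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Devil's staircase of the circle map
#'
#' Dressed winding number w as a function of the bare winding number over a
#' grid, iterated for all grid points simultaneously. At k = 1 the curve is
#' the complete Devil's staircase: non-decreasing, with a plateau at every
#' rational whose width shrinks with the denominator.
#'
#' @param omega_grid ascending numeric grid, typically spanning \[0, 1\].
#' @inheritParams circle_map_orbit
#' @return A `staircase_curve` data frame with columns `x` (omega) and
#'   `y` (w).
#' @examples
#' s <- devils_staircase(seq(0, 1, length.out = 101), k = 0)
#' all.equal(s$x, s$y)  # identity line at k = 0
#' @export
devils_staircase <- function(omega_grid, k = 1, theta0 = 0.2,
                             n_transient = 1000, n_iter = 10000) {
  if (is.unsorted(omega_grid)) stop("omega_grid must be ascending")
  if (k < 0) stop("k must be >= 0")
  cc <- k / (2 * pi)
  th <- rep(theta0, length(omega_grid))
  for (j in seq_len(n_transient)) th <- th + omega_grid + cc * sin(2 * pi * th)
  start <- th
  for (j in seq_len(n_iter)) th <- th + omega_grid + cc * sin(2 * pi * th)
  out <- data.frame(x = omega_grid, y = (th - start) / n_iter)
  class(out) <- c("staircase_curve", "data.frame")
  out
}

#' Width of a mode-locking plateau
#'
#' Measures the omega-interval over which the dressed winding number equals
#' `p/q`. Because w(omega) is non-decreasing for k <= 1, the two plateau
#' edges are found by monotone bisection: the left edge is the infimum of
#' `{omega : w(omega) >= p/q - tol}` and the right edge the supremum of
#' `{omega : w(omega) <= p/q + tol}`; the reported width is the edge
#' difference minus the `2 * tol` slack this definition introduces
#' (clamped at 0, so the unlocked k = 0 case reports exactly 0). The
#' initial bracket is grown outward from p/q until w clears the target on
#' both sides; at k = 1 the tongues bend, so the bracket — not omega = p/q
#' itself — is what must contain the plateau.
#'
#' At critical coupling the locked orbit is approached algebraically, so a
#' winding estimate over the whole counted window carries a transient
#' phase slip of order `0.1 / n_iter` that can exceed `tol`. Membership is
#' therefore classified from the rotation measured over the last
#' `tail` iterations only (where the residual slip is of order
#' `0.1 * tail / n_iter^2`, negligible at the defaults), guarded by a
#' loose (1e-3) check on the full-window estimate.
#'
#' @param p,q reduced fraction (gcd 1) with 0 <= p/q <= 1.
#' @param k coupling strength.
#' @param tol tolerance on w when classifying a point as on-plateau
#'   (default 1e-6).
#' @param depth bisection depth per edge (default 50; stops early once the
#'   bracket is below 1e-12).
#' @param step initial outward step when bracketing (default 0.05 / q).
#' @param tail number of final iterations over which the on-plateau
#'   rotation is measured (default 2000).
#' @inheritParams circle_map_orbit
#' @return The plateau width (>= 0; 0 when no locking interval exists, as
#'   at k = 0).
#' @export
plateau_width <- function(p, q, k = 1, tol = 1e-6, depth = 50,
                          step = 0.05 / q, theta0 = 0.2,
                          n_transient = 1000, n_iter = 50000, tail = 2000) {
  if (q < 1 || p < 0 || p != round(p) || q != round(q))
    stop("p/q must be a fraction with positive integer denominator")
  if (p > 0 && gcd_int(p, q) != 1)
    stop("p/q must be in lowest terms")
  target <- p / q
  # the tail span must hold an integer number of q-cycles, else a locked
  # period-q orbit's partial cycle biases the tail estimate by O(1/tail)
  tail <- q * max(1L, floor(min(tail, n_iter) / q))
  wn <- function(om) {
    th <- circle_map_orbit(om, k, theta0, n_transient, n_iter)
    b <- length(th)
    w_full <- (th[b] - th[n_transient + 1]) / n_iter
    w_tail <- (th[b] - th[b - tail]) / tail
    # guard: far off the plateau the tail estimate alone could alias
    if (abs(w_full - target) > 1e-3) w_full else w_tail
  }
  # bracket: om_lo with w < target - tol, om_hi with w > target + tol
  om_lo <- target
  while (wn(om_lo) >= target - tol) {
    om_lo <- om_lo - step
    if (om_lo < target - 0.5) break
  }
  om_hi <- target
  while (wn(om_hi) <= target + tol) {
    om_hi <- om_hi + step
    if (om_hi > target + 0.5) break
  }
  bisect <- function(lo, hi, above) {
    # `above(om)` is FALSE at lo, TRUE at hi and monotone; returns the
    # transition point
    for (i in seq_len(depth)) {
      mid <- (lo + hi) / 2
      if (above(mid)) hi <- mid else lo <- mid
      if (hi - lo < 1e-12) break
    }
    (lo + hi) / 2
  }
  left <- bisect(om_lo, om_hi, function(om) wn(om) >= target - tol)
  right <- bisect(om_lo, om_hi, function(om) wn(om) > target + tol)
  width <- max(0, right - left - 2 * tol)
  if (width < tol) 0 else width   # below tol the edges are not resolved
}

#' Compare an empirical staircase with a theoretical one
#'
#' Normalizes both curves to the unit square (x linearly mapped to
#' \[0, 1\] over its span, y already cumulative/winding in \[0, 1\]),
#' resamples them on a common grid by linear interpolation, and reports the
#' sup-norm difference and the Pearson correlation. Because the published
#' axis convention for the empirical curve is ambiguous, the comparison is
#' also run with the empirical axes transposed (x and y swapped); both
#' correlations are reported.
#'
#' @param empirical,theoretical `staircase_curve` data frames (columns `x`,
#'   `y`), each with at least 2 rows and a non-degenerate x-range.
#' @param n_grid number of resampling points (default 512).
#' @return A list of class `staircase_comparison`: `sup_norm`, `pearson_r`,
#'   `pearson_r_transposed`, `grid` (data frame with `x`, `empirical`,
#'   `theoretical`).
#' @export
compare_staircases <- function(empirical, theoretical, n_grid = 512) {
  norm_x <- function(s) {
    if (nrow(s) < 2L) stop("staircase needs at least 2 points")
    rng <- range(s$x)
    if (diff(rng) == 0) stop("degenerate staircase: zero x-range")
    data.frame(x = (s$x - rng[1]) / diff(rng), y = s$y)
  }
  e <- norm_x(empirical)
  t_ <- norm_x(theoretical)
  g <- seq(0, 1, length.out = n_grid)
  ey <- stats::approx(e$x, e$y, xout = g, rule = 2, ties = mean)$y
  ty <- stats::approx(t_$x, t_$y, xout = g, rule = 2, ties = mean)$y
  # transposed orientation: read the empirical curve as x(y)
  et <- norm_x(data.frame(x = empirical$y, y = empirical$x)[order(empirical$y), ])
  et$y <- (et$y - min(et$y)) / diff(range(et$y))
  ety <- stats::approx(et$x, et$y, xout = g, rule = 2, ties = mean)$y
  structure(list(
    sup_norm = max(abs(ey - ty)),
    pearson_r = stats::cor(ey, ty),
    pearson_r_transposed = stats::cor(ety, ty),
    grid = data.frame(x = g, empirical = ey, theoretical = ty)),
    class = "staircase_comparison")
}

#' @export
print.staircase_comparison <- function(x, ...) {
  cat(sprintf(paste0("<staircase_comparison> sup-norm %.4f, Pearson r %.4f",
                     " (transposed empirical axes: %.4f)\n"),
              x$sup_norm, x$pearson_r, x$pearson_r_transposed))
  invisible(x)
}
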