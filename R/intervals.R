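#' Just-intonation interval catalog
#'
#' The reference catalog of 31 in-octave intervals used to label recurrence
#' peaks: the reduced rational `num/den`, the conventional name, and a short
#' label for the named consonances. `reported_recurrence` and
#' `reported_ratio` record the recurrence magnitudes and peak positions of
#' the original windowed analysis; they serve as a rank-order reference
#' only, since absolute recurrence values depend on the (unrecoverable)
#' radius convention of the software that produced them. One catalog quirk
#' is preserved as published: the ratio 1.8567 row is listed under 15/8
#' although 15/8 = 1.875 matches only the 1.8747 row; it carries
#' `caveat = TRUE`.
#'
#' @return A data frame with columns `reported_recurrence`,
#'   `reported_ratio`, `label`, `num`, `den`, `name`, `caveat`.
#' @export
interval_catalog <- function() {
  cat_df <- data.frame(
    reported_recurrence = c(100.0, 89.1, 45.2, 30.6, 29.6, 23.4, 19.9, 18.5,
                            16.3, 15.4, 15.1, 14.2, 11.9, 11.7, 11.5, 10.1,
                            9.8, 9.7, 9.4, 9.3, 9.1, 9.1, 8.7, 8.6, 7.8,
                            7.7, 7.6, 7.1, 6.8, 6.8, 6.7),
    reported_ratio = c(0.9999, 2.0006, 1.5003, 1.3335, 1.6671, 1.2495,
                       1.7499, 1.2003, 1.4007, 1.5999, 1.8003, 1.1667,
                       1.2855, 1.8339, 1.1427, 1.4283, 1.1247, 1.7139,
                       1.5711, 1.1115, 1.8567, 1.2219, 1.1006, 1.3755,
                       1.8747, 1.2999, 1.6251, 1.0911, 1.8891, 1.1823,
                       1.4451),
    label = c("U", "P8", "P5", "P4", "M6", "M3", "H7", "m3", "", "m6",
              "m7", "", "", "", "", "", "Mt", "", "", "mt", "", "", "",
              "", "M7", "", "", "", "", "", "D5"),
    num = c(1, 2, 3, 4, 5, 5, 7, 6, 7, 8, 9, 7, 9, 11, 8, 10, 9, 12, 11,
            10, 15, 11, 11, 11, 15, 13, 13, 12, 17, 13, 13),
    den = c(1, 1, 2, 3, 3, 4, 4, 5, 5, 5, 5, 6, 7, 6, 7, 7, 8, 7, 7, 9,
            8, 9, 10, 8, 8, 10, 8, 11, 9, 11, 9),
    name = c("Unison", "Octave", "Perfect fifth", "Perfect fourth",
             "Major sixth", "Major third", "Harmonic seventh",
             "Minor third", "Septimal", "Minor sixth", "Just minor seventh",
             "Septimal minor third", "Septimal major third",
             "Undecimal neutral seventh", "Septimal whole tone",
             "Euler's tritone", "Major whole tone", "Septimal major sixth",
             "Undecimal augmented fifth", "Minor whole tone",
             "Classic major seventh", "Undecimal neutral third", "4/5 tone",
             "Undecimal semi-augmented fourth", "Classic major seventh",
             "Tridecimal semi-diminished fourth", "Tridecimal neutral sixth",
             "3/4 tone", "Septendecimal minor third", "Tridecimal minor third",
             "Tridecimal diminished fifth"),
    stringsAsFactors = FALSE)
  cat_df$caveat <- FALSE
  cat_df$caveat[cat_df$reported_ratio == 1.8567] <- TRUE
  cat_df
}

#' Reference consonance order
#'
#' The ten named consonances in decreasing order of consonance as ranked in
#' classical harmony: U > P8 > P5 > P4 > M6 > M3 > m3 > m6 > m7 > M7.
#'
#' @return Character vector of the ten labels, most consonant first.
#' @export
consonance_reference <- function() {
  c("U", "P8", "P5", "P4", "M6", "M3", "m3", "m6", "m7", "M7")
}

#' Best rational approximation with bounded denominator
#'
#' Finds the reduced fraction `num/den` with `den <= max_denominator`
#' minimizing `|ratio - num/den|` (a bounded Stern–Brocot / Farey search);
#' exact ties go to the smaller denominator.
#'
#' @param ratio a positive real, typically in \[1, 2.2\] for in-octave work.
#' @param max_denominator largest admissible denominator (default 11,
#'   covering every denominator in the interval catalog).
#' @return A list with `num`, `den`, `value` (= num/den) and `error`
#'   (= |ratio - value|).
#' @examples
#' match_rational(1.5003)  # 3/2
#' @export
match_rational <- function(ratio, max_denominator = 11) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
    stop("`ratio` must be a single positive number")
  if (max_denominator < 1) stop("max_denominator must be >= 1")
  best <- NULL
  for (den in seq_len(max_denominator)) {
    num <- round(ratio * den)
    if (num < 1) num <- 1
    if (gcd_int(num, den) != 1L) next
    err <- abs(ratio - num / den)
    if (is.null(best) || err < best$error - 1e-15) {
      best <- list(num = num, den = den, value = num / den, error = err)
    }
  }
  best
}

#' Frova's consonance index
#'
#' For a reduced interval ratio m/n, the index `(m + n) / (m * n)`: larger
#' for simpler (more consonant) ratios, symmetric in m and n.
#'
#' @param num,den positive integers forming a reduced fraction
#'   (`gcd(num, den) = 1`).
#' @return The index value.
#' @examples
#' frova_index(3, 2)  # 5/6
#' @export
frova_index <- function(num, den) {
  if (any(den == 0)) stop("denominator must be non-zero")
  if (any(num < 1) || any(den < 1) ||
      any(num != round(num)) || any(den != round(den)))
    stop("num and den must be positive integers")
  if (any(mapply(gcd_int, num, den) != 1))
    stop("num/den must be in lowest terms")
  (num + den) / (num * den)
}
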