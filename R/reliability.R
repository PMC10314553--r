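#' Repeated-measures container for intra-rater reliability
#'
#' Pairs of repeated measurements of one variable by the same examiner
#' (two sessions), used for Dahlberg casual error, relative random error
#' and intraclass correlation.
#'
#' @param m1,m2 numeric vectors of first/second-session measurements, same
#'   length and units.
#' @param variable variable name (carried to reports).
#' @return An object of class `repeated_measures`.
#' @export
repeated_measures <- function(m1, m2, variable = "measure") {
  m1 <- as.numeric(m1); m2 <- as.numeric(m2)
  if (length(m1) != length(m2)) stop("sessions have different lengths", call. = FALSE)
  if (!all(is.finite(m1)) || !all(is.finite(m2))) {
    stop("repeated measurements must be finite", call. = FALSE)
  }
  structure(list(m1 = m1, m2 = m2, n = length(m1), variable = variable),
            class = "repeated_measures")
}

#' Dahlberg casual (random) measurement error
#'
#' `d = sqrt( sum((m1_i - m2_i)^2) / (2 n) )`, in the units of the
#' measurement. Under i.i.d. Gaussian session errors with standard
#' deviation sigma, `d` estimates sigma.
#'
#' @param rm A [repeated_measures()] with `n >= 2`.
#' @return Dahlberg error (same units as the measurements).
#' @export
dahlberg_error <- function(rm) {
  stopifnot(inherits(rm, "repeated_measures"))
  if (rm$n < 2L) stop("Dahlberg error needs at least 2 measurement pairs", call. = FALSE)
  sqrt(sum((rm$m1 - rm$m2)^2) / (2 * rm$n))
}

#' Relative random error
#'
#' Dahlberg error expressed as a percentage of the magnitude of the
#' measurement, with the grand mean of both sessions as the (symmetric)
#' denominator.
#'
#' @param rm A [repeated_measures()].
#' @return Percentage (0-100 scale).
#' @export
relative_error_percent <- function(rm) {
  gm <- mean(c(rm$m1, rm$m2))
  if (abs(gm) < 1e-12) stop("relative error undefined: grand mean is zero", call. = FALSE)
  100 * dahlberg_error(rm) / gm
}

#' Intraclass correlation for a single fixed rater
#'
#' Single-measurement ICC from the two-way ANOVA decomposition of the
#' subject x session table (k = 2 sessions). The default `ICC(3,1)`
#' (two-way mixed, consistency) is the standard intra-rater form:
#' `(MS_subjects - MS_error) / (MS_subjects + (k-1) MS_error)`. The
#' absolute-agreement form `ICC(2,1)` additionally penalises session mean
#' shifts.
#'
#' @param rm A [repeated_measures()] with `n >= 3`.
#' @param model `"ICC31"` (consistency, default) or `"ICC21"` (absolute
#'   agreement).
#' @return ICC coefficient in `[-1, 1]`.
#' @export
icc_single_rater <- function(rm, model = c("ICC31", "ICC21")) {
  model <- match.arg(model)
  stopifnot(inherits(rm, "repeated_measures"))
  n <- rm$n; k <- 2
  if (n < 3L) stop("ICC needs at least 3 subjects", call. = FALSE)
  x <- cbind(rm$m1, rm$m2)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_r < 1e-12 * max(1, abs(grand))^2 && ms_r <= ms_e) {
    stop("degenerate ICC: no between-subject variance", call. = FALSE)
  }
  switch(model,
         ICC31 = (ms_r - ms_e) / (ms_r + (k - 1) * ms_e),
         ICC21 = (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n))
}

#' Reliability report over several variables
#'
#' Convenience wrapper producing the per-variable reliability table
#' (n, ICC, Dahlberg error in original units, relative random error %).
#'
#' @param data a data frame with one row per subject.
#' @param pairs a named list mapping a variable name to the two session
#'   column names, e.g. `list(total_volume = c("tv_s1", "tv_s2"))`.
#' @param model ICC model, see [icc_single_rater()].
#' @return A tibble with columns `variable`, `n`, `icc`, `dahlberg`,
#'   `relative_error_pct`.
#' @export
reliability_report <- function(data, pairs, model = "ICC31") {
  purrr::map_dfr(names(pairs), function(v) {
    cols <- pairs[[v]]
    rm <- repeated_measures(data[[cols[1]]], data[[cols[2]]], variable = v)
    tibble::tibble(variable = v, n = rm$n,
                   icc = icc_single_rater(rm, model = model),
                   dahlberg = dahlberg_error(rm),
                   relative_error_pct = relative_error_percent(rm))
  })
}
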