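new_am_test <- function(method, statistic, df, p, estimate = NA_real_,
                        n = NA_integer_, extra = list()) {
  out <- c(list(method = method, statistic = statistic, df = df,
                p_two_sided = p, estimate = estimate, n = n), extra)
  class(out) <- "am_test"
  out
}

#' @export
print.am_test <- function(x, ...) {
  cat(sprintf("<%s> statistic %.4g, df %s, p %.4g, estimate %.4g\n",
              x$method, x$statistic, paste(signif(x$df, 6), collapse = "/"),
              x$p_two_sided, x$estimate))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a test result
#' @param x An `am_test` object.
#' @param ... unused.
#' @return A one-row tibble with `method`, `statistic`, `df`, `p.value`,
#'   `estimate`, `n`.
#' @method tidy am_test
#' @export
tidy.am_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 df = paste(signif(x$df, 8), collapse = "/"),
                 p.value = x$p_two_sided, estimate = x$estimate,
                 n = paste(x$n, collapse = "/"))
}

as_summary_triple <- function(x) {
  if (is.list(x) && all(c("n", "mean", "sd") %in% names(x))) {
    c(n = x$n, mean = x$mean, sd = x$sd)
  } else if (is.numeric(x) && length(x) == 3L && !is.null(names(x)) &&
             all(c("n", "mean", "sd") %in% names(x))) {
    x[c("n", "mean", "sd")]
  } else if (is.numeric(x)) {
    c(n = length(x), mean = mean(x), sd = stats::sd(x))
  } else {
    stop("sample must be a numeric vector or a summary (n, mean, sd)", call. = FALSE)
  }
}

#' Two-sample Student t test
#'
#' Pooled-variance two-sample t test (the classical "Student's t"), two
#' sided, with `df = n1 + n2 - 2`. Accepts raw numeric vectors or summary
#' triples `list(n=, mean=, sd=)`/named `c(n=, mean=, sd=)`, so printed
#' group summaries can be tested directly. A Welch option is available for
#' unequal variances.
#'
#' @param a,b samples or summary triples.
#' @param welch use the Welch (unequal-variance) form instead of pooled.
#' @return An `am_test` (estimate = mean difference `a - b`).
#' @export
student_t <- function(a, b, welch = FALSE) {
  sa <- as_summary_triple(a); sb <- as_summary_triple(b)
  n1 <- sa[["n"]]; n2 <- sb[["n"]]
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  m1 <- sa[["mean"]]; m2 <- sb[["mean"]]; s1 <- sa[["sd"]]; s2 <- sb[["sd"]]
  if (welch) {
    se2 <- s1^2 / n1 + s2^2 / n2
    if (se2 < 1e-24) stop("zero variance in both groups", call. = FALSE)
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 < 1e-24) stop("zero pooled variance", call. = FALSE)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  new_am_test(if (welch) "Welch t" else "Student t", tstat, df,
              2 * stats::pt(-abs(tstat), df), estimate = m1 - m2, n = c(n1, n2))
}

#' Paired t test
#'
#' One-sample t test on within-subject differences `x1 - x0`, two-sided,
#' `df = n - 1`.
#'
#' @param x0,x1 equal-length numeric vectors (baseline and follow-up).
#' @return An `am_test` (estimate = mean difference `x1 - x0`).
#' @export
paired_t <- function(x0, x1) {
  if (length(x0) != length(x1)) stop("paired samples must have equal length", call. = FALSE)
  n <- length(x0)
  if (n < 2) stop("paired t needs n >= 2", call. = FALSE)
  d <- x1 - x0
  sd_d <- stats::sd(d)
  if (sd_d < 1e-12 * max(1, abs(mean(d)))) {
    stop("zero variance of paired differences: paired t test is undefined", call. = FALSE)
  }
  tstat <- mean(d) / (sd_d / sqrt(n))
  new_am_test("paired t", tstat, n - 1, 2 * stats::pt(-abs(tstat), n - 1),
              estimate = mean(d), n = n)
}

# cache of Monte-Carlo null distributions of the Lilliefors statistic,
# keyed by (n, reps, seed)
.lilliefors_cache <- new.env(parent = emptyenv())

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  f <- stats::pnorm(z)
  max(max(seq_len(n) / n - f), max(f - (seq_len(n) - 1) / n))
}

#' Kolmogorov-Smirnov normality test (Lilliefors-corrected)
#'
#' KS statistic against a normal distribution with mean and SD estimated
#' from the sample. Because the parameters are estimated, the plain KS
#' p-value is anticonservative; the default p-value is computed by a seeded
#' Lilliefors Monte-Carlo simulation of the null distribution (cached per
#' sample size). `corrected = FALSE` returns the plain KS p-value instead.
#'
#' @param x numeric sample, `n >= 5`, non-constant.
#' @param reps Monte-Carlo replicates (default 10000).
#' @param seed seed for the null simulation.
#' @param corrected use the Lilliefors Monte-Carlo p (default) or plain KS.
#' @return An `am_test` (statistic = D, estimate = D).
#' @export
ks_normality <- function(x, reps = 10000, seed = 1L, corrected = TRUE) {
  n <- length(x)
  if (n < 5) stop("normality test needs n >= 5", call. = FALSE)
  if (stats::sd(x) < 1e-12) stop("constant sample: normality test undefined", call. = FALSE)
  D <- lilliefors_stat(x)
  if (!corrected) {
    p <- stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value
  } else {
    key <- sprintf("n%d_r%d_s%d", n, reps, as.integer(seed))
    if (is.null(.lilliefors_cache[[key]])) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(as.integer(seed))
      sims <- matrix(stats::rnorm(n * reps), n, reps)
      .lilliefors_cache[[key]] <- apply(sims, 2, lilliefors_stat)
    }
    null_d <- .lilliefors_cache[[key]]
    p <- (1 + sum(null_d >= D)) / (reps + 1)
  }
  new_am_test(if (corrected) "Lilliefors KS" else "KS", D, n, p, estimate = D, n = n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Age-adjusted group comparison (ANCOVA)
#'
#' Linear model `y ~ group + age` with Type II F tests, the
#' "multifactorial" adjustment used to control the age imbalance between
#' treatment groups: returns the age-factor and group-factor p-values.
#'
#' @param y numeric response.
#' @param group two-level factor (or coercible).
#' @param age numeric covariate.
#' @return A list with `p_age`, `p_group` and the fitted `model`.
#' @export
ancova_group_age <- function(y, group, age) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("ANCOVA expects exactly two groups", call. = FALSE)
  if (anyNA(y) || anyNA(age)) stop("ANCOVA inputs must not contain missing values", call. = FALSE)
  if (stats::sd(age) < 1e-12) stop("rank-deficient ANCOVA: age is constant", call. = FALSE)
  fit <- stats::lm(y ~ group + age)
  aov2 <- car::Anova(fit, type = 2)
  list(p_age = aov2["age", "Pr(>F)"], p_group = aov2["group", "Pr(>F)"], model = fit)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, non-constant.
#' @return An `am_test` (statistic = t, estimate = r).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("correlation needs n >= 3", call. = FALSE)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  new_am_test("Pearson correlation", unname(ct$statistic), unname(ct$parameter),
              ct$p.value, estimate = unname(ct$estimate), n = length(x))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction (which is what reproduces the printed
#' sex-distribution p-value of the study cohort), `df = 1`.
#'
#' @param counts 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return An `am_test` (statistic = chi-square).
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi-square undefined: zero margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  new_am_test("Pearson chi-square", unname(ct$statistic), unname(ct$parameter),
              ct$p.value, estimate = unname(ct$statistic), n = rowSums(counts))
}

#' Paired t-test sample size from the noncentral t distribution
#'
#' Smallest `n >= 2` whose two-sided paired t test reaches the target power:
#' power is computed exactly from the noncentral t distribution with
#' noncentrality `(mean_diff / sd_diff) * sqrt(n)` and `df = n - 1`.
#'
#' @param mean_diff expected mean within-pair difference (measurement units).
#' @param sd_diff standard deviation of the differences (same units).
#' @param alpha two-sided significance level (default 0.05, i.e. 95%
#'   confidence).
#' @param power target power (default 0.90).
#' @return Minimum number of pairs (integer), with attribute `power` (the
#'   attained power).
#' @examples
#' sample_size_paired_t(1261.6, 1476.2)
#' @export
sample_size_paired_t <- function(mean_diff, sd_diff, alpha = 0.05, power = 0.90) {
  if (sd_diff <= 0) stop("sd_diff must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  }
  d <- abs(mean_diff) / sd_diff
  if (d == 0) stop("zero effect size: no finite sample size reaches the target power",
                   call. = FALSE)
  pw <- function(n) {
    cv <- stats::qt(1 - alpha / 2, n - 1)
    ncp <- d * sqrt(n)
    1 - stats::pt(cv, n - 1, ncp) + stats::pt(-cv, n - 1, ncp)
  }
  n <- 2L
  while (pw(n) < power) n <- n + 1L
  structure(n, power = pw(n))
}

#' Classify treatment success from the apnea-hypopnea index
#'
#' Success is defined as a post-treatment AHI below 10 events/hour **or** a
#' reduction of at least 50% from baseline; everything else is
#' `"partial/failure"`. Vectorised.
#'
#' @param ahi_t0,ahi_t1 nonnegative AHI values (events/hour) before/after.
#' @return Character vector, `"success"` or `"partial/failure"`.
#' @export
classify_treatment_success <- function(ahi_t0, ahi_t1) {
  if (any(ahi_t0 < 0, na.rm = TRUE) || any(ahi_t1 < 0, na.rm = TRUE)) {
    stop("AHI values must be nonnegative", call. = FALSE)
  }
  ifelse(ahi_t1 < 10 | ahi_t1 <= 0.5 * ahi_t0, "success", "partial/failure")
}
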