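#' Plot paired airway changes
#'
#' Paired T0/T1 spaghetti plot of an airway variable by group, the standard
#' display for within-subject treatment change.
#'
#' @param measurements wide measurement table (see [simulate_cohort()]).
#' @param variable airway variable stem, e.g. `"superior_volume"`.
#' @return A ggplot object.
#' @export
plot_airway_change <- function(measurements, variable = "total_volume") {
  c0 <- paste0(variable, "_t0"); c1 <- paste0(variable, "_t1")
  if (!all(c(c0, c1) %in% names(measurements))) {
    stop(sprintf("columns %s/%s not found", c0, c1), call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    measurements[, c("patient_id", "group", c0, c1)],
    cols = c(c0, c1), names_to = "timepoint", values_to = "value")
  long$timepoint <- ifelse(endsWith(long$timepoint, "_t0"), "T0", "T1")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$value,
                                     group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_point(size = 1) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$group), fun = mean,
                          geom = "line", linewidth = 1.2, colour = "firebrick") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = variable,
                  title = sprintf("Paired %s change by treatment group", variable)) +
    ggplot2::theme_minimal()
}

#' Autoplot a study report
#'
#' Volcano-style overview of the report's between-group and paired tests:
#' one point per test, -log10 p against the table it came from.
#'
#' @param object A `study_report` from [run_study()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, ...) {
  rows <- dplyr::bind_rows(
    tibble::tibble(table = "between-group", label = object$airway$variable,
                   p = object$airway$p_a),
    tibble::tibble(table = "paired", label = object$airway_paired$variable,
                   p = object$airway_paired$p_b),
    tibble::tibble(table = "mandible", label = object$mandible$variable,
                   p = object$mandible$p_a),
    tibble::tibble(table = "correlation",
                   label = paste(object$correlations$variable,
                                 object$correlations$against, sep = " ~ "),
                   p = object$correlations$p))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$table, y = -log10(.data$p))) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Study report: test overview (dashed line: alpha = 0.05)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
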