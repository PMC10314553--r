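#' Measure one patient: airway at both timepoints and mandibular change
#'
#' Full per-patient path: orient T0 into the head frame built from its
#' cranial landmarks, register T1 to T0 (landmark least-squares by default,
#' voxel-based or a provided transform on request), apply the transforms,
#' then measure the delimited airway regions at both timepoints and the
#' mandibular displacement/rotations.
#'
#' @param t0_mask,t1_mask [voxel_mask()] objects (or `NULL` to skip airway
#'   measurement).
#' @param t0_landmarks,t1_landmarks [landmark_set()] objects with
#'   orientation + airway (+ mandible, if present) landmarks.
#' @param registration `"landmark"` (default), `"voxel"` or `"provided"`.
#' @param transform the T1 -> T0 [rigid_transform()] when
#'   `registration = "provided"`.
#' @param registration_names landmark names for the landmark strategy
#'   (default: the cranial orientation landmarks plus basion when present).
#' @param settings settings list passed to [register_voxel_rigid()].
#' @return A list of class `patient_measurement`: `airway_t0`, `airway_t1`
#'   (see [measure_airway()]), `mandible` (see [measure_mandible()], `NULL`
#'   when mandible landmarks are absent), and provenance (`orientation`,
#'   `registration` transforms).
#' @export
measure_patient <- function(t0_mask, t1_mask, t0_landmarks, t1_landmarks,
                            registration = c("landmark", "voxel", "provided"),
                            transform = NULL, registration_names = NULL,
                            settings = list()) {
  registration <- match.arg(registration)
  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE)
    })
  }
  frame <- stage("orientation", build_head_frame(t0_landmarks))
  lm0 <- apply_transform(t0_landmarks, frame$transform, frame = "oriented")

  reg <- stage("registration", switch(registration,
    landmark = {
      names <- registration_names %||%
        intersect(c("Ba", "PoR", "PoL", "OrR", "OrL"),
                  intersect(rownames(t0_landmarks$points), rownames(t1_landmarks$points)))
      register_landmarks_rigid(t1_landmarks, t0_landmarks, names)
    },
    voxel = {
      if (is.null(t0_mask) || is.null(t1_mask)) {
        stop("voxel registration requires both masks", call. = FALSE)
      }
      register_voxel_rigid(t0_mask, t1_mask, settings = settings)
    },
    provided = transform %||% stop("registration = 'provided' needs a transform",
                                   call. = FALSE)))
  to_common_t1 <- rt_compose(frame$transform, reg)
  lm1 <- apply_transform(t1_landmarks, to_common_t1, frame = "oriented")

  airway_t0 <- airway_t1 <- NULL
  if (!is.null(t0_mask)) {
    m0 <- transform_grid(t0_mask, frame$transform)
    airway_t0 <- stage("airway T0", measure_airway(m0, lm0))
  }
  if (!is.null(t1_mask)) {
    m1 <- transform_grid(t1_mask, to_common_t1)
    airway_t1 <- stage("airway T1", measure_airway(m1, lm1))
  }
  mandible <- NULL
  if (all(required_landmarks("mandible") %in% rownames(lm0$points)) &&
      all(required_landmarks("mandible") %in% rownames(lm1$points))) {
    mandible <- stage("mandible", measure_mandible(lm0, lm1))
  }
  structure(list(airway_t0 = airway_t0, airway_t1 = airway_t1,
                 mandible = mandible,
                 orientation = frame$transform, registration = reg),
            class = "patient_measurement")
}

#' Whole-study statistical report
#'
#' Reproduces the structure of the study's result tables from a cohort
#' manifest and wide per-patient measurement table (as produced by
#' [simulate_cohort()], or assembled from [measure_patient()] results):
#'
#' * `demographics`: per-variable group means +/- SD, Student t p-values,
#'   and the sex-distribution chi-square;
#' * `airway`: per airway variable and timepoint, group means, between-group
#'   Student t (`p_a`), age-adjusted ANCOVA (`p_c` age, `p_d` group), and
#'   the within-group paired t (`p_b`);
#' * `mandible`: change-score group comparison with the same columns;
#' * `correlations`: per group, Pearson r and p of each change variable
#'   against the anteroposterior and superoinferior B-point displacements.
#'
#' All tests are two-sided; no multiplicity adjustment is applied (the
#' number of tests run is recorded in `glance()`).
#'
#' @param manifest cohort manifest tibble (see [read_cohort_manifest()]).
#' @param measurements wide measurement table with `patient_id` keys.
#' @param welch use Welch instead of pooled t for between-group tests.
#' @return A list of class `study_report` with the four tibbles.
#' @export
run_study <- function(manifest, measurements, welch = FALSE) {
  df <- dplyr::inner_join(manifest, measurements,
                          by = intersect(c("patient_id", "group"),
                                         intersect(names(manifest), names(measurements))))
  groups <- sort(unique(df$group))
  if (length(groups) != 2L) stop("study requires exactly two groups", call. = FALSE)
  if (any(table(df$group) < 2L)) stop("each group needs >= 2 patients", call. = FALSE)
  g1 <- df$group == groups[1]; g2 <- df$group == groups[2]

  msd <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  n_tests <- 0L

  demo_vars <- intersect(c("age", "weight", "height", "bmi"), names(df))
  demographics <- purrr::map_dfr(demo_vars, function(v) {
    tt <- student_t(df[[v]][g1], df[[v]][g2], welch = welch)
    n_tests <<- n_tests + 1L
    tibble::tibble(variable = v,
                   !!groups[1] := msd(df[[v]][g1]),
                   !!groups[2] := msd(df[[v]][g2]),
                   p_a = tt$p_two_sided)
  })
  if ("sex" %in% names(df)) {
    tab <- table(factor(df$group, groups), factor(df$sex, c("M", "F")))
    cs <- chi_square_2x2(unclass(tab))
    n_tests <- n_tests + 1L
    demographics <- dplyr::bind_rows(
      tibble::tibble(variable = "sex (M/F)",
                     !!groups[1] := paste(tab[1, ], collapse = "/"),
                     !!groups[2] := paste(tab[2, ], collapse = "/"),
                     p_a = cs$p_two_sided),
      demographics)
  }

  airway_vars <- c("total_volume", "total_area", "superior_volume",
                   "superior_area", "inferior_volume", "inferior_area")
  airway_vars <- airway_vars[paste0(airway_vars, "_t0") %in% names(df)]
  airway <- purrr::map_dfr(airway_vars, function(v) {
    purrr::map_dfr(c("T0", "T1"), function(tp) {
      col <- paste0(v, "_", tolower(tp))
      an <- ancova_group_age(df[[col]], df$group, df$age)
      tt <- student_t(df[[col]][g1], df[[col]][g2], welch = welch)
      n_tests <<- n_tests + 2L
      tibble::tibble(variable = v, timepoint = tp,
                     !!groups[1] := msd(df[[col]][g1]),
                     !!groups[2] := msd(df[[col]][g2]),
                     p_a = tt$p_two_sided, p_c = an$p_age, p_d = an$p_group)
    })
  })
  paired <- purrr::map_dfr(airway_vars, function(v) {
    purrr::map_dfr(groups, function(g) {
      sel <- df$group == g
      pt <- paired_t(df[[paste0(v, "_t0")]][sel], df[[paste0(v, "_t1")]][sel])
      n_tests <<- n_tests + 1L
      tibble::tibble(variable = v, group = g, p_b = pt$p_two_sided,
                     mean_change = pt$estimate)
    })
  })

  mand_vars <- intersect(c("delta_ap", "delta_si", "ramus_pitch_mean",
                           "anterior_pitch_mean"), names(df))
  mandible <- purrr::map_dfr(mand_vars, function(v) {
    an <- ancova_group_age(df[[v]], df$group, df$age)
    tt <- student_t(df[[v]][g1], df[[v]][g2], welch = welch)
    n_tests <<- n_tests + 2L
    tibble::tibble(variable = v,
                   !!groups[1] := msd(df[[v]][g1]),
                   !!groups[2] := msd(df[[v]][g2]),
                   p_a = tt$p_two_sided, p_c = an$p_age, p_d = an$p_group)
  })

  corr_rows <- list()
  for (g in groups) {
    sel <- df$group == g
    yvars <- c(
      if (all(paste0("superior_volume_", c("t0", "t1")) %in% names(df)))
        c(d_superior_volume = NA) else NULL,
      if (all(paste0("inferior_volume_", c("t0", "t1")) %in% names(df)))
        c(d_inferior_volume = NA) else NULL,
      if ("ramus_pitch_mean" %in% names(df)) c(ramus_pitch_mean = NA) else NULL,
      if ("anterior_pitch_mean" %in% names(df)) c(anterior_pitch_mean = NA) else NULL)
    for (yv in names(yvars)) {
      y <- if (startsWith(yv, "d_")) {
        base <- sub("^d_", "", yv)
        df[[paste0(base, "_t1")]][sel] - df[[paste0(base, "_t0")]][sel]
      } else df[[yv]][sel]
      for (xv in intersect(c("delta_ap", "delta_si"), names(df))) {
        ct <- pearson_correlation(df[[xv]][sel], y)
        n_tests <- n_tests + 1L
        corr_rows[[length(corr_rows) + 1L]] <-
          tibble::tibble(group = g, variable = yv, against = xv,
                         r = ct$estimate, p = ct$p_two_sided)
      }
    }
  }
  correlations <- dplyr::bind_rows(corr_rows)

  structure(list(demographics = demographics, airway = airway,
                 airway_paired = paired, mandible = mandible,
                 correlations = correlations,
                 n_tests = n_tests, groups = groups,
                 n_per_group = as.integer(table(df$group)[groups])),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> groups %s (n = %s); %d tests, no multiplicity adjustment\n",
              paste(x$groups, collapse = " vs "),
              paste(x$n_per_group, collapse = "/"), x$n_tests))
  cat("\n-- demographics --\n"); print(x$demographics)
  cat("\n-- airway (between groups / ANCOVA) --\n"); print(x$airway, n = Inf)
  cat("\n-- airway (within group, paired) --\n"); print(x$airway_paired, n = Inf)
  cat("\n-- mandible --\n"); print(x$mandible)
  cat("\n-- correlations --\n"); print(x$correlations, n = Inf)
  invisible(x)
}

#' Glance at a study report
#' @param x A `study_report`.
#' @param ... unused.
#' @return One-row tibble: group sizes, number of tests, counts of
#'   significant results at alpha = 0.05 per table.
#' @method glance study_report
#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(
    n_group1 = x$n_per_group[1], n_group2 = x$n_per_group[2],
    n_tests = x$n_tests,
    sig_between = sum(x$airway$p_a < 0.05) + sum(x$mandible$p_a < 0.05),
    sig_paired = sum(x$airway_paired$p_b < 0.05),
    sig_correlations = sum(x$correlations$p < 0.05))
}

#' Write a study report to disk
#'
#' Emits one CSV per table plus a JSON mirror of the whole report.
#' @param report A `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("demographics", "airway", "airway_paired", "mandible", "correlations")) {
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(report[c("demographics", "airway", "airway_paired",
                                "mandible", "correlations", "n_tests")],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
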