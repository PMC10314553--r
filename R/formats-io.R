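#' Read a 3D Slicer fiducial file
#'
#' Reads Slicer FCSV (`# Markups fiducial file version ...`) or markups JSON
#' fiducial files into a [landmark_set()]. Coordinates are converted to the
#' internal RAS millimetre frame honouring the file's declared coordinate
#' system (FCSV `# CoordinateSystem = 0`/`RAS` vs `1`/`LPS`; JSON
#' `coordinateSystem` field). Labels are normalized to the canonical landmark
#' names via the alias table (see [landmark_aliases()]).
#'
#' @param path path to a `.fcsv` or `.json`/`.mrk.json` fiducial file.
#' @param task optional task name; when given, the presence of the landmarks
#'   required for that task is validated (see [required_landmarks()]).
#' @param aliases alias table, a data frame with columns `alias`, `canonical`.
#' @param patient_id,timepoint identifiers attached to the returned set.
#' @return A [landmark_set()] in RAS mm.
#' @export
read_landmarks <- function(path, task = NULL, aliases = landmark_aliases(),
                           patient_id = NA_character_, timepoint = NA_character_) {
  if (!file.exists(path)) stop(sprintf("fiducial file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  lm <- if (grepl("Markups fiducial file version", first, fixed = TRUE)) {
    read_fcsv(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE) || grepl("^\\s*\\{", first)) {
    read_markups_json(path)
  } else {
    stop(sprintf("unrecognised fiducial format: %s", path), call. = FALSE)
  }
  nm <- normalize_landmark_names(rownames(lm), aliases)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate landmark names after alias normalization: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")), call. = FALSE)
  }
  rownames(lm) <- nm
  out <- landmark_set(lm, frame = "scanner", patient_id = patient_id,
                      timepoint = timepoint)
  if (!is.null(task)) validate_landmarks(out, task)
  out
}

# FCSV: comment header lines, then CSV rows
# id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID
read_fcsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) stop(sprintf("no fiducial rows in %s", path), call. = FALSE)
  cs_line <- grep("CoordinateSystem", header, value = TRUE)
  lps <- FALSE
  if (length(cs_line)) {
    cs <- trimws(sub(".*=", "", cs_line[1]))
    lps <- cs %in% c("1", "LPS", "lps")
  }
  fields <- strsplit(body, ",")
  pts <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  labels <- vapply(fields, function(f) if (length(f) >= 12) trimws(f[12]) else "", character(1))
  if (any(!nzchar(labels))) stop(sprintf("unlabelled fiducial in %s", path), call. = FALSE)
  if (any(!is.finite(pts))) stop(sprintf("non-numeric coordinates in %s", path), call. = FALSE)
  if (lps) pts[, 1:2] <- -pts[, 1:2]
  rownames(pts) <- labels
  pts
}

read_markups_json <- function(path) {
  obj <- jsonlite::read_json(path)
  mk <- obj$markups
  if (is.null(mk) || !length(mk)) stop(sprintf("no markups in %s", path), call. = FALSE)
  pts_list <- list()
  for (m in mk) {
    cs <- m$coordinateSystem %||% "LPS"
    for (cp in m$controlPoints) {
      p <- as.numeric(unlist(cp$position))
      if (identical(toupper(cs), "LPS")) p[1:2] <- -p[1:2]
      pts_list[[cp$label]] <- p
    }
  }
  pts <- do.call(rbind, pts_list)
  rownames(pts) <- names(pts_list)
  pts
}

#' Write landmarks as Slicer FCSV
#'
#' Writes in the RAS dialect (`# CoordinateSystem = 0`), so the file
#' round-trips exactly through [read_landmarks()].
#' @param lm A [landmark_set()].
#' @param path output `.fcsv` path.
#' @param coordinate_system `"RAS"` (default) or `"LPS"` output dialect.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path, coordinate_system = c("RAS", "LPS")) {
  coordinate_system <- match.arg(coordinate_system)
  pts <- lm$points
  if (coordinate_system == "LPS") pts[, 1:2] <- -pts[, 1:2]
  header <- c("# Markups fiducial file version = 4.11",
              sprintf("# CoordinateSystem = %d", if (coordinate_system == "RAS") 0L else 1L),
              "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
  rows <- sprintf("vtkMRMLMarkupsFiducialNode_%d,%.9g,%.9g,%.9g,0,0,0,1,1,1,0,%s,,",
                  seq_len(nrow(pts)), pts[, 1], pts[, 2], pts[, 3], rownames(pts))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a UTF-8 CSV with one row per patient and columns
#' `patient_id`, `group` (`MAD`/`MMA`), `sex` (`M`/`F`), `age`, `weight`
#' (kg), `height` (m), `bmi` (kg/m^2), optional `ahi_t0`, `ahi_t1` and
#' optional per-timepoint file-path columns (`mask_t0`, `mask_t1`,
#' `landmarks_t0`, `landmarks_t1`).
#'
#' @param path CSV path.
#' @param quiet suppress the group-count message.
#' @return A tibble of typed rows.
#' @export
read_cohort_manifest <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("patient_id", "group", "sex", "age", "weight", "height", "bmi")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("manifest missing columns: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stop(sprintf("duplicated patient_id: %s",
                 paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", ")),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(df$group), c("MAD", "MMA"))
  if (length(bad_group)) {
    stop(sprintf("unknown group label(s): %s", paste(bad_group, collapse = ", ")),
         call. = FALSE)
  }
  for (col in c("age", "weight", "height", "bmi")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]]))) {
      stop(sprintf("non-numeric values in column '%s'", col), call. = FALSE)
    }
    df[[col]] <- v
  }
  ok <- stats::complete.cases(df[, c("weight", "height", "bmi")])
  if (any(ok)) {
    computed <- df$weight[ok] / df$height[ok]^2
    off <- abs(computed - df$bmi[ok]) / computed > 0.05
    if (any(off)) {
      warning(sprintf("BMI inconsistent with weight/height (>5%%) for: %s (computed %s)",
                      paste(df$patient_id[ok][off], collapse = ", "),
                      paste(sprintf("%.1f", computed[off]), collapse = ", ")),
              call. = FALSE)
    }
  }
  if (!quiet) {
    counts <- table(df$group)
    message(sprintf("manifest: %s", paste(sprintf("%s:%d", names(counts), counts),
                                          collapse = ", ")))
  }
  df
}

#' Write and re-read measurement tables
#'
#' Writes homogeneous per-patient measurement records as CSV and, alongside,
#' a JSON mirror (`<path>.json` next to a `.csv` path). Missing values are
#' serialized as empty cells / JSON nulls and read back as `NA`. Numeric
#' round trip is exact to better than 1e-9.
#'
#' @param records a data frame of measurement rows.
#' @param path output CSV path.
#' @return `write_measurements`: `path`, invisibly. `read_measurements`: a
#'   tibble.
#' @export
write_measurements <- function(records, path) {
  records <- as.data.frame(records)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format_numeric_full(records), path, row.names = FALSE, na = "")
  jsonlite::write_json(records, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  invisible(path)
}

format_numeric_full <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      v <- sprintf("%.17g", df[[col]])
      v[is.na(df[[col]])] <- NA_character_
      df[[col]] <- v
    }
  }
  df
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
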