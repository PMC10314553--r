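#' Named 3D anatomical landmark sets
#'
#' A `landmark_set` holds named anatomical points in millimetre world
#' coordinates (internal RAS frame: +X right, +Y anterior, +Z superior),
#' together with a frame tag and patient/timepoint identifiers.
#'
#' Canonical landmark names used by the pipeline:
#' * airway delimitation: `Ba` (basion), `PNS` (posterior nasal spine),
#'   `C2I`, `C4S` (cervical vertebra levels);
#' * mandible: `CoR`, `CoL` (condylion), `GoR`, `GoL` (gonion), `B` (B point);
#' * head orientation: `PoR`, `PoL` (porion), `OrR`, `OrL` (orbitale).
#'
#' @param points an n x 3 numeric matrix with landmark names as rownames,
#'   or a data frame with columns `name`, `x`, `y`, `z`.
#' @param frame free-text tag for the coordinate frame (e.g. `"scanner"`,
#'   `"oriented"`).
#' @param patient_id,timepoint identifiers carried through to outputs;
#'   `timepoint` is `"T0"` or `"T1"` when known.
#' @return An object of class `landmark_set`.
#' @examples
#' lm <- landmark_set(rbind(Ba = c(0, -40, 40), PNS = c(0, 10, 40)))
#' lm_get(lm, "Ba")
#' @export
landmark_set <- function(points, frame = "scanner",
                         patient_id = NA_character_, timepoint = NA_character_) {
  if (is.data.frame(points)) {
    m <- as.matrix(points[, c("x", "y", "z")])
    rownames(m) <- as.character(points$name)
    points <- m
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("landmark points must be n x 3", call. = FALSE)
  nm <- rownames(points)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("all landmarks must be named (rownames)", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate landmark names: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")), call. = FALSE)
  }
  if (!all(is.finite(points))) stop("landmark coordinates must be finite", call. = FALSE)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, frame = frame,
                 patient_id = patient_id, timepoint = timepoint),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks, frame '%s'%s\n",
              nrow(x$points), x$frame,
              if (!is.na(x$patient_id)) paste0(", patient ", x$patient_id) else ""))
  print(round(x$points, 3))
  invisible(x)
}

#' @method as_tibble landmark_set
#' @export
as_tibble.landmark_set <- function(x, ...) {
  tibble::tibble(name = rownames(x$points),
                 x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
                 frame = x$frame, patient_id = x$patient_id,
                 timepoint = x$timepoint)
}

#' Extract landmark coordinates
#' @param lm A `landmark_set`.
#' @param name Landmark name.
#' @return Length-3 numeric vector (mm).
#' @export
lm_get <- function(lm, name) {
  if (!name %in% rownames(lm$points)) {
    stop(sprintf("landmark '%s' not present", name), call. = FALSE)
  }
  lm$points[name, ]
}

#' Required landmark names per measurement task
#' @param task one of `"airway"`, `"mandible"`, `"orientation"`.
#' @return Character vector of canonical names.
#' @export
required_landmarks <- function(task = c("airway", "mandible", "orientation")) {
  switch(match.arg(task),
         airway = c("Ba", "PNS", "C2I", "C4S"),
         mandible = c("CoR", "CoL", "GoR", "GoL", "B"),
         orientation = c("PoR", "PoL", "OrR", "OrL"))
}

#' Validate that a landmark set supports a task
#'
#' @param lm A `landmark_set`.
#' @param task measurement task, see [required_landmarks()].
#' @return `lm` invisibly; errors listing the missing names otherwise.
#' @export
validate_landmarks <- function(lm, task = c("airway", "mandible", "orientation")) {
  task <- match.arg(task)
  need <- required_landmarks(task)
  missing <- setdiff(need, rownames(lm$points))
  if (length(missing)) {
    stop(sprintf("missing landmarks for %s task: {%s}", task,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(lm)
}

#' Default landmark alias table
#'
#' Slicer fiducial labels are free text; this editable table maps common
#' spellings to the canonical names. The packaged copy lives at
#' `system.file("extdata", "landmark_aliases.csv", package = "airwaymorph")`.
#' @return A tibble with columns `alias`, `canonical`.
#' @export
landmark_aliases <- function() {
  path <- system.file("extdata", "landmark_aliases.csv", package = "airwaymorph")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

normalize_landmark_names <- function(names, aliases = landmark_aliases()) {
  key <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  map <- stats::setNames(aliases$canonical, key(aliases$alias))
  hit <- unname(map[key(names)])
  ifelse(is.na(hit), names, hit)
}
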