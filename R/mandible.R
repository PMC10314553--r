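#' B-point anteroposterior and superoinferior displacement
#'
#' Displacement of the mandibular B point between timepoints, in the
#' oriented common frame: `delta_ap = Y(T1) - Y(T0)` (positive = anterior)
#' and `delta_si = Z(T1) - Z(T0)` (positive = superior).
#'
#' @param lm_t0,lm_t1 [landmark_set()] objects containing `B`, both in the
#'   oriented common frame.
#' @return Named numeric vector `c(delta_ap, delta_si)` in mm.
#' @export
b_point_displacement <- function(lm_t0, lm_t1) {
  for (lm in list(lm_t0, lm_t1)) {
    if (!"B" %in% rownames(lm$points)) {
      stop("missing landmark B for displacement measurement", call. = FALSE)
    }
  }
  b0 <- lm_get(lm_t0, "B"); b1 <- lm_get(lm_t1, "B")
  c(delta_ap = b1[["y"]] - b0[["y"]], delta_si = b1[["z"]] - b0[["z"]])
}

#' Signed pitch rotation of a directed line
#'
#' Pitch is rotation about the left-right (+X) axis. Each directed line
#' `p -> q` is projected onto the midsagittal (YZ) plane; its orientation
#' angle is `atan2(dz, dy)` and the returned rotation is the change
#' `theta(T1) - theta(T0)` wrapped to `(-180, 180]` degrees. Positive
#' rotations take +Y (anterior) toward +Z (superior), i.e. counterclockwise
#' viewed from the patient's right; a mandible swinging open (anterior
#' landmark moving inferiorly) gives a negative (clockwise) pitch.
#'
#' @param p_t0,q_t0,p_t1,q_t1 length-3 points (mm, oriented frame).
#' @return Signed pitch rotation in degrees, in `(-180, 180]`.
#' @export
line_pitch_rotation <- function(p_t0, q_t0, p_t1, q_t1) {
  ang <- function(p, q) {
    v <- q - p
    if (sqrt(v[2]^2 + v[3]^2) < 1e-9) {
      stop("degenerate line: p -> q is parallel to the X axis after sagittal projection",
           call. = FALSE)
    }
    atan2(v[3], v[2])
  }
  unname(wrap_deg((ang(p_t1, q_t1) - ang(p_t0, q_t0)) * 180 / pi))
}

wrap_deg <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

#' Mandibular displacement and pitch rotations between timepoints
#'
#' Computes the full mandibular change record: B-point displacement, and
#' signed pitch rotations of the ramus line (`Co -> Go`) and the anterior
#' line (`Co -> B`) on each side, plus side means. Sign convention:
#' positive = counterclockwise viewed from the patient's right (anterior
#' landmark rotating superiorly); negative = clockwise. With this
#' convention an oral-appliance-style opening rotation is negative and a
#' surgical counterclockwise rotation is positive.
#'
#' @param lm_t0,lm_t1 [landmark_set()] objects with `CoR`, `CoL`, `GoR`,
#'   `GoL`, `B` at both timepoints, in the oriented common frame.
#' @return A one-row tibble (class `mandible_change`) with columns
#'   `patient_id`, `delta_ap`, `delta_si` (mm), `ramus_pitch_R`,
#'   `ramus_pitch_L`, `anterior_pitch_R`, `anterior_pitch_L`,
#'   `ramus_pitch_mean`, `anterior_pitch_mean` (degrees) and
#'   `sign_convention`.
#' @export
measure_mandible <- function(lm_t0, lm_t1) {
  validate_landmarks(lm_t0, "mandible")
  validate_landmarks(lm_t1, "mandible")
  disp <- b_point_displacement(lm_t0, lm_t1)
  pitch <- function(p_name, q_name) {
    line_pitch_rotation(lm_get(lm_t0, p_name), lm_get(lm_t0, q_name),
                        lm_get(lm_t1, p_name), lm_get(lm_t1, q_name))
  }
  rr <- pitch("CoR", "GoR"); rl <- pitch("CoL", "GoL")
  ar <- pitch("CoR", "B"); al <- pitch("CoL", "B")
  out <- tibble::tibble(
    patient_id = mask_patient_id(lm_t0),
    delta_ap = disp[["delta_ap"]],
    delta_si = disp[["delta_si"]],
    ramus_pitch_R = rr, ramus_pitch_L = rl,
    anterior_pitch_R = ar, anterior_pitch_L = al,
    ramus_pitch_mean = (rr + rl) / 2,
    anterior_pitch_mean = (ar + al) / 2,
    sign_convention = "+ = counterclockwise from patient right (anterior up)")
  class(out) <- c("mandible_change", class(out))
  out
}
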