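#' Construct an oriented plane
#' @param point a point on the plane (mm).
#' @param normal plane normal; normalized internally.
#' @return An object of class `airway_plane` with unit `normal`, `point` and
#'   the signed `offset` (`normal . point`).
#' @export
airway_plane <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("plane normal is zero", call. = FALSE)
  normal <- normal / nn
  structure(list(point = point, normal = normal, offset = sum(normal * point)),
            class = "airway_plane")
}

#' Landmark-defined oropharyngeal delimiting planes
#'
#' Builds the three parallel planes that delimit the oropharynx in the
#' oriented head frame: the base plane contains `Ba` and `PNS` and is
#' perpendicular to the midsagittal plane (its normal lies in the sagittal
#' YZ plane with a positive Z component, which makes the two-point "Ba-PNS
#' plane" unique); the `C2I` and `C4S` planes share that normal and pass
#' through their landmarks. Signed offsets along the common normal must be
#' ordered base > C2I > C4S (superior to inferior).
#'
#' @param lm A [landmark_set()] with `Ba`, `PNS`, `C2I`, `C4S`, expressed in
#'   the oriented head frame.
#' @return A list of class `delimiting_planes` with elements `base`, `c2i`,
#'   `c4s` ([airway_plane()] objects sharing one normal) and `normal`.
#' @examples
#' lm <- landmark_set(rbind(Ba = c(0, -40, 40), PNS = c(0, 10, 40),
#'                          C2I = c(0, 0, 15), C4S = c(0, 0, -10)))
#' build_delimiting_planes(lm)$normal
#' @export
build_delimiting_planes <- function(lm) {
  validate_landmarks(lm, "airway")
  ba <- lm_get(lm, "Ba"); pns <- lm_get(lm, "PNS")
  u <- pns - ba
  if (sqrt(sum(u^2)) < 1e-9) stop("degenerate base plane: Ba and PNS coincide", call. = FALSE)
  if (sqrt(u[2]^2 + u[3]^2) < 1e-9) {
    stop("degenerate base plane: Ba-PNS is perpendicular to the sagittal plane", call. = FALSE)
  }
  normal <- c(0, -u[3], u[2])           # in-sagittal perpendicular to Ba->PNS
  if (normal[3] < 0) normal <- -normal  # superior side positive
  if (abs(normal[3]) < 1e-12) {
    stop("degenerate base plane: Ba-PNS is vertical in the sagittal plane", call. = FALSE)
  }
  base <- airway_plane(ba, normal)
  c2i <- airway_plane(lm_get(lm, "C2I"), normal)
  c4s <- airway_plane(lm_get(lm, "C4S"), normal)
  if (!(base$offset > c2i$offset && c2i$offset > c4s$offset)) {
    stop(sprintf(paste0("plane ordering violated: expected base > C2I > C4S along the ",
                        "superior normal, got offsets %.2f, %.2f, %.2f"),
                 base$offset, c2i$offset, c4s$offset), call. = FALSE)
  }
  structure(list(base = base, c2i = c2i, c4s = c4s, normal = base$normal),
            class = "delimiting_planes")
}

check_parallel_slab <- function(upper, lower) {
  d <- abs(sum(upper$normal * lower$normal))
  if (abs(d - 1) > 1e-9) stop("slab planes are not parallel", call. = FALSE)
  lo <- sum(upper$normal * lower$point)  # lower offset along upper's normal
  if (upper$offset <= lo) {
    stop("upper plane must be strictly superior to lower plane", call. = FALSE)
  }
  c(lower = lo, upper = upper$offset)
}

#' Region volume between two parallel planes
#'
#' Counts foreground voxels whose centre has a signed offset in the
#' half-open slab `[lower, upper)` along the common (superior-positive)
#' normal, times the voxel volume. The half-open convention makes adjacent
#' slabs partition the mask exactly.
#'
#' @param mask A [voxel_mask()].
#' @param upper,lower [airway_plane()] objects with parallel normals; `upper`
#'   strictly superior.
#' @return Volume in mm^3.
#' @export
region_volume <- function(mask, upper, lower) {
  rng <- check_parallel_slab(upper, lower)
  w <- voxel_world(mask)
  if (nrow(w) == 0L) return(0)
  d <- as.numeric(w %*% upper$normal)
  sum(d >= rng["lower"] & d < rng["upper"]) * voxel_volume(mask)
}

#' Triangulated surface of a mask
#'
#' Extracts the iso-surface of the mask at level 0.5 by marching tetrahedra
#' on a Gaussian-smoothed copy of the binary grid (smoothing recovers
#' sub-voxel surface placement from binary data; `sigma_vox = 0` meshes the
#' raw binary field).
#'
#' @param mask A [voxel_mask()].
#' @param sigma_vox smoothing bandwidth in voxels (default 1).
#' @return A list with `triangles` (n x 9 world-coordinate matrix), `areas`
#'   (mm^2 per triangle) and `centroids` (n x 3, mm).
#' @export
mask_surface <- function(mask, sigma_vox = 1) {
  field <- .gauss_smooth3d(as.numeric(mask$grid), dim(mask$grid), sigma_vox)
  tri0 <- .march_tets(field, dim(mask$grid), 0.5)
  if (nrow(tri0) == 0L) {
    return(list(triangles = matrix(numeric(0), 0, 9),
                areas = numeric(0), centroids = matrix(numeric(0), 0, 3)))
  }
  A <- mask$affine
  to_world <- function(v0) {
    # zero-based voxel -> world
    sweep((v0 + 1) %*% t(A[1:3, 1:3]), 2, A[1:3, 4], "+")
  }
  p1 <- to_world(tri0[, 1:3, drop = FALSE])
  p2 <- to_world(tri0[, 4:6, drop = FALSE])
  p3 <- to_world(tri0[, 7:9, drop = FALSE])
  e1 <- p2 - p1; e2 <- p3 - p1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  areas <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  centroids <- (p1 + p2 + p3) / 3
  list(triangles = cbind(p1, p2, p3), areas = areas, centroids = centroids)
}

#' Region surface area between two parallel planes
#'
#' Sums the areas of iso-surface triangles whose centroid lies in the
#' half-open slab `[lower, upper)`. The artificial planar caps created by
#' the delimitation are **not** added: only the mask's own (lateral) surface
#' is measured. Centroid assignment makes adjacent slabs partition the total
#' surface exactly.
#'
#' @inheritParams region_volume
#' @param surface optional precomputed [mask_surface()] (reused by
#'   [measure_airway()] across the three regions).
#' @param sigma_vox smoothing bandwidth passed to [mask_surface()].
#' @return Area in mm^2.
#' @export
region_surface_area <- function(mask, upper, lower, surface = NULL, sigma_vox = 1) {
  rng <- check_parallel_slab(upper, lower)
  surface <- surface %||% mask_surface(mask, sigma_vox = sigma_vox)
  if (!length(surface$areas)) return(0)
  d <- as.numeric(surface$centroids %*% upper$normal)
  sum(surface$areas[d >= rng["lower"] & d < rng["upper"]])
}

#' Oropharyngeal region volumes and surface areas
#'
#' Delimits the airway mask by the Ba-PNS, C2I and C4S planes and measures:
#' total region (base to C4S), superior oropharynx (base to C2I) and
#' inferior oropharynx (C2I to C4S). Volumes use half-open voxel-centre
#' slabs, so `superior + inferior == total` exactly; areas use centroid
#' slab assignment of the shared iso-surface, with the same partition
#' property, and exclude cut caps.
#'
#' @param mask A [voxel_mask()] in the oriented, registered frame.
#' @param landmarks A [landmark_set()] in the same frame with the airway
#'   landmarks.
#' @param sigma_vox surface smoothing bandwidth (voxels).
#' @return A one-row tibble (class `airway_measurement`) with columns
#'   `patient_id`, `timepoint`, `total_volume`, `superior_volume`,
#'   `inferior_volume` (mm^3), `total_area`, `superior_area`,
#'   `inferior_area` (mm^2).
#' @export
measure_airway <- function(mask, landmarks, sigma_vox = 1) {
  planes <- build_delimiting_planes(landmarks)
  w <- voxel_world(mask)
  d <- as.numeric(w %*% planes$normal)
  vv <- voxel_volume(mask)
  in_total <- d >= planes$c4s$offset & d < planes$base$offset
  if (!any(in_total)) {
    warning("airway mask does not intersect the delimited region; measurements are zero",
            call. = FALSE)
    vols <- c(total = 0, superior = 0, inferior = 0)
    areas <- c(total = 0, superior = 0, inferior = 0)
  } else {
    sup_v <- sum(d >= planes$c2i$offset & d < planes$base$offset) * vv
    inf_v <- sum(d >= planes$c4s$offset & d < planes$c2i$offset) * vv
    # the half-open slabs partition the voxel set, so total is the exact sum
    vols <- c(total = sup_v + inf_v, superior = sup_v, inferior = inf_v)
    surf <- mask_surface(mask, sigma_vox = sigma_vox)
    ds <- as.numeric(surf$centroids %*% planes$normal)
    areas <- c(total = sum(surf$areas[ds >= planes$c4s$offset & ds < planes$base$offset]),
               superior = sum(surf$areas[ds >= planes$c2i$offset & ds < planes$base$offset]),
               inferior = sum(surf$areas[ds >= planes$c4s$offset & ds < planes$c2i$offset]))
  }
  out <- tibble::tibble(
    patient_id = mask_patient_id(landmarks),
    timepoint = landmarks$timepoint,
    total_volume = vols[["total"]],
    superior_volume = vols[["superior"]],
    inferior_volume = vols[["inferior"]],
    total_area = areas[["total"]],
    superior_area = areas[["superior"]],
    inferior_area = areas[["inferior"]])
  class(out) <- c("airway_measurement", class(out))
  out
}

mask_patient_id <- function(lm) {
  if (!is.null(lm$patient_id) && !is.na(lm$patient_id)) lm$patient_id else NA_character_
}
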