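#' Rigid (6-DOF) spatial transforms
#'
#' A `rigid_transform` is a proper rotation plus a translation mapping world
#' coordinates (millimetres) between two frames: `y = R x + t`. The class is
#' closed under composition and inversion and is used for head orientation
#' and T1-to-T0 registration.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(2, -3, 1))
#' rt_apply(t1, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation))) {
    stop("rigid_transform: non-finite entries", call. = FALSE)
  }
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-8) {
    stop(sprintf("rigid_transform: rotation not orthonormal (max deviation %.2e)", err),
         call. = FALSE)
  }
  if (det(rotation) < 0) {
    stop("rigid_transform: rotation has determinant -1 (reflection)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rt_rotation_angle(x)
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity transform
#' @return A `rigid_transform` that maps every point to itself.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` returns the transform applying `b` first, then `a`
#' (i.e. `x -> a(b(x))`).
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_invert <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to points
#' @param t A `rigid_transform`.
#' @param pts numeric vector of length 3 or an n x 3 matrix of points (mm).
#' @return Transformed points, same shape as the input.
#' @export
rt_apply <- function(t, pts) {
  if (is.null(dim(pts))) {
    as.numeric(t$rotation %*% pts) + t$translation
  } else {
    sweep(pts %*% t(t$rotation), 2L, t$translation, "+")
  }
}

#' Rotation angle of a transform
#' @param t A `rigid_transform`.
#' @return Magnitude of the rotation, degrees in `[0, 180]`.
#' @export
rt_rotation_angle <- function(t) {
  c_ <- (sum(diag(t$rotation)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' Rotation about a coordinate axis
#'
#' Right-handed rotation by `angle_deg` degrees about `+X`, `+Y` or `+Z`,
#' optionally about a centre point rather than the origin.
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param center length-3 point the axis passes through (default origin).
#' @return A `rigid_transform`.
#' @export
rt_axis_rotation <- function(angle_deg, axis = c("x", "y", "z"),
                             center = c(0, 0, 0)) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  cs <- cos(a); sn <- sin(a)
  R <- switch(axis,
    x = matrix(c(1, 0, 0, 0, cs, sn, 0, -sn, cs), 3, 3),
    y = matrix(c(cs, 0, -sn, 0, 1, 0, sn, 0, cs), 3, 3),
    z = matrix(c(cs, sn, 0, -sn, cs, 0, 0, 0, 1), 3, 3))
  center <- as.numeric(center)
  rigid_transform(R, center - as.numeric(R %*% center))
}

#' Build a transform from Euler angles and a translation
#'
#' Parameterisation used by the voxel registration optimiser: intrinsic
#' rotations applied in X, then Y, then Z order about a centre point.
#' @param angles_deg length-3 rotation angles (degrees) about x, y, z.
#' @param translation length-3 translation (mm).
#' @param center rotation centre (mm).
#' @return A `rigid_transform`.
#' @export
rt_from_params <- function(angles_deg, translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  r <- rt_compose(rt_axis_rotation(angles_deg[3], "z"),
                  rt_compose(rt_axis_rotation(angles_deg[2], "y"),
                             rt_axis_rotation(angles_deg[1], "x")))
  center <- as.numeric(center)
  rigid_transform(r$rotation,
                  center - as.numeric(r$rotation %*% center) + as.numeric(translation))
}

#' Convert a transform to a 4x4 homogeneous matrix
#' @param t A `rigid_transform`.
#' @return A 4x4 numeric matrix.
#' @export
rt_as_matrix <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$translation
  m
}

#' Build a transform from a 4x4 homogeneous matrix
#' @param m A 4x4 matrix whose upper-left block is a proper rotation.
#' @return A `rigid_transform`.
#' @export
rt_from_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4L, 4L)))
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Serialize / deserialize transforms as JSON
#'
#' Transforms are stored as row-major 4x4 homogeneous matrices.
#' @param t A `rigid_transform`.
#' @param path file path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns a `rigid_transform`.
#' @export
write_transform <- function(t, path) {
  m <- rt_as_matrix(t)
  jsonlite::write_json(list(matrix = as.numeric(t(m)), order = "row-major"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rt_from_matrix(matrix(as.numeric(obj$matrix), 4, 4, byrow = TRUE))
}
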