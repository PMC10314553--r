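#' Oriented head frame from cranial landmarks
#'
#' Builds the standard cephalometric head orientation from the porion and
#' orbitale landmarks so that the Frankfurt horizontal plane is perpendicular
#' to +Z, the midsagittal plane is `{X = 0}`, and the transporionic axis is
#' parallel to +X. The Frankfurt plane is fit through the two porions and the
#' mean of the available orbitale landmarks (averaging left/right makes the
#' three-point plane deterministic); the frame origin is the mid-transporionic
#' point.
#'
#' @param lm A [landmark_set()] containing `PoR`, `PoL` and at least one of
#'   `OrR`, `OrL`.
#' @return A list of class `head_frame` with elements `transform` (the
#'   [rigid_transform()] mapping input coordinates into the oriented frame)
#'   and `origin` (midpoint of the porions, input coordinates).
#' @examples
#' lm <- landmark_set(rbind(PoR = c(-60, 0, 0), PoL = c(60, 0, 0),
#'                          OrR = c(-30, 70, 0), OrL = c(30, 70, 0)))
#' build_head_frame(lm)$transform
#' @export
build_head_frame <- function(lm) {
  nms <- rownames(lm$points)
  if (!all(c("PoR", "PoL") %in% nms)) {
    stop("head frame requires PoR and PoL", call. = FALSE)
  }
  or_names <- intersect(c("OrR", "OrL"), nms)
  if (!length(or_names)) {
    stop("head frame requires at least one orbitale landmark (OrR/OrL)", call. = FALSE)
  }
  por <- lm_get(lm, "PoR"); pol <- lm_get(lm, "PoL")
  or_mid <- colMeans(lm$points[or_names, , drop = FALSE])

  xv <- pol - por
  if (sqrt(sum(xv^2)) < 1e-6) stop("degenerate head frame: porions coincide", call. = FALSE)
  x_axis <- xv / sqrt(sum(xv^2))

  v2 <- or_mid - por
  zn <- c(x_axis[2] * v2[3] - x_axis[3] * v2[2],
          x_axis[3] * v2[1] - x_axis[1] * v2[3],
          x_axis[1] * v2[2] - x_axis[2] * v2[1])
  nz <- sqrt(sum(zn^2))
  if (nz < 1e-6) stop("degenerate head frame: porions and orbitale collinear", call. = FALSE)
  z_axis <- zn / nz
  if (z_axis[3] < 0) z_axis <- -z_axis   # Frankfurt normal oriented superiorly

  y_axis <- c(z_axis[2] * x_axis[3] - z_axis[3] * x_axis[2],
              z_axis[3] * x_axis[1] - z_axis[1] * x_axis[3],
              z_axis[1] * x_axis[2] - z_axis[2] * x_axis[1])
  y_axis <- y_axis / sqrt(sum(y_axis^2))
  x_axis <- c(y_axis[2] * z_axis[3] - y_axis[3] * z_axis[2],
              y_axis[3] * z_axis[1] - y_axis[1] * z_axis[3],
              y_axis[1] * z_axis[2] - y_axis[2] * z_axis[1])

  origin <- unname((por + pol) / 2)
  rot <- rbind(x_axis, y_axis, z_axis)
  dimnames(rot) <- NULL
  transform <- rigid_transform(rot, as.numeric(-rot %*% origin))
  structure(list(transform = transform, origin = origin), class = "head_frame")
}

#' @export
print.head_frame <- function(x, ...) {
  cat("<head_frame>\n  origin:", sprintf("%.3f", x$origin), "\n")
  print(x$transform)
  invisible(x)
}
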