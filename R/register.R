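#' Least-squares rigid landmark registration
#'
#' Closed-form (SVD) rigid fit of shared named landmarks: the returned
#' transform maps `source` coordinates onto `target` so as to minimise the
#' sum of squared distances over the named points, with no scaling and no
#' reflection. This is the deterministic registration path used by default
#' in the pipeline; voxel-based cranial registration is offered as
#' [register_voxel_rigid()].
#'
#' @param source,target [landmark_set()] objects sharing at least 3
#'   non-collinear landmark names.
#' @param names landmark names to fit over; default is all shared names.
#' @return A [rigid_transform()] with attribute `rms` (root-mean-square
#'   residual, mm).
#' @export
register_landmarks_rigid <- function(source, target, names = NULL) {
  shared <- intersect(rownames(source$points), rownames(target$points))
  names <- names %||% shared
  missing <- setdiff(names, shared)
  if (length(missing)) {
    stop(sprintf("landmarks not shared by both sets: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (length(names) < 3L) stop("rigid registration needs >= 3 shared landmarks", call. = FALSE)
  S <- source$points[names, , drop = FALSE]
  T_ <- target$points[names, , drop = FALSE]
  cs <- colMeans(S); ct <- colMeans(T_)
  Sc <- sweep(S, 2, cs); Tc <- sweep(T_, 2, ct)
  sv <- svd(crossprod(Sc, Tc))
  # collinearity: rank of the centred configuration
  if (svd(Sc)$d[2] < 1e-9 * max(svd(Sc)$d[1], 1)) {
    stop("landmarks are collinear; rigid registration is underdetermined", call. = FALSE)
  }
  d <- det(sv$v %*% t(sv$u))
  if (d < 0) {
    if (sv$d[3] > 1e-8 * sv$d[1]) {
      stop("best rigid fit requires a reflection; check landmark sides/labels", call. = FALSE)
    }
    sv$v[, 3] <- -sv$v[, 3]
  }
  R <- sv$v %*% t(sv$u)
  t_ <- ct - as.numeric(R %*% cs)
  out <- rigid_transform(R, t_)
  res <- sweep(S %*% t(R), 2, t_, "+") - T_
  attr(out, "rms") <- sqrt(mean(rowSums(res^2)))
  out
}

#' Voxel-based rigid registration
#'
#' Recovers the 6-DOF transform mapping `moving` world coordinates onto
#' `fixed` by maximising normalized cross-correlation between
#' Gaussian-smoothed intensity fields, with a multi-resolution
#' derivative-free (Nelder-Mead) search. For binary masks the smoothed-field
#' correlation behaves as a soft label-overlap score. A `region_mask`
#' (e.g. cranial base) restricts the similarity metric when given. The
#' procedure is deterministic given fixed settings.
#'
#' @param fixed,moving [voxel_mask()] objects (or grayscale volumes wrapped
#'   as masks) with overlapping fields of view.
#' @param region_mask optional [voxel_mask()] on the fixed grid restricting
#'   the metric.
#' @param init optional initial [rigid_transform()] (moving -> fixed).
#' @param settings list: `sigma_vox` smoothing in voxels (default 2),
#'   `levels` downsampling factors coarse-to-fine (default `c(2, 1)`),
#'   `maxit` Nelder-Mead iterations per level (default 600), `max_points`
#'   metric sample budget (default 20000).
#' @return A [rigid_transform()] mapping moving -> fixed world coordinates,
#'   with attributes `metric` (final correlation) and `converged`.
#' @export
register_voxel_rigid <- function(fixed, moving, region_mask = NULL, init = NULL,
                                 settings = list()) {
  s <- utils::modifyList(list(sigma_vox = 2, levels = c(2, 1), maxit = 1500,
                              max_points = 20000), settings)
  if (!is.null(region_mask) && sum(region_mask$grid) == 0L) {
    stop("empty region_mask", call. = FALSE)
  }
  fx_s <- .gauss_smooth3d(as.numeric(fixed$grid), dim(fixed$grid), s$sigma_vox)
  mv_s <- .gauss_smooth3d(as.numeric(moving$grid), dim(moving$grid), s$sigma_vox)

  keep <- fx_s > 0.01
  if (!is.null(region_mask)) keep <- keep & (region_mask$grid == 1L)
  idx <- which(array(keep, dim(fixed$grid)), arr.ind = TRUE)
  if (nrow(idx) < 100L) stop("too few voxels in the similarity region", call. = FALSE)

  cfix <- colMeans(voxel_world(fixed))
  cmov <- colMeans(voxel_world(moving))
  # initial parameters: provided transform, else centroid alignment
  par0 <- c(0, 0, 0, cmov - cfix)
  if (!is.null(init)) {
    par0 <- params_from_rt(rt_invert(init), cfix)
  }

  obj_factory <- function(pts_world, fvals) {
    fvals <- fvals - mean(fvals)
    fnorm <- sqrt(sum(fvals^2))
    function(par) {
      t_inv <- rt_from_params(par[1:3], par[4:6], cfix)
      src <- rt_apply(t_inv, pts_world)
      mvals <- .trilinear_sample(mv_s, dim(moving$grid), world_to_voxel0(moving, src))
      mvals <- mvals - mean(mvals)
      mnorm <- sqrt(sum(mvals^2))
      if (mnorm < 1e-12) return(1)
      1 - sum(fvals * mvals) / (fnorm * mnorm)
    }
  }

  par <- par0
  conv <- TRUE
  for (lev in s$levels) {
    sel <- idx[(idx[, 1] %% lev == 0) & (idx[, 2] %% lev == 0) & (idx[, 3] %% lev == 0), ,
               drop = FALSE]
    if (nrow(sel) > s$max_points) {
      sel <- sel[seq(1, nrow(sel), length.out = s$max_points), , drop = FALSE]
    }
    pts_world <- voxel_world(fixed, sel)
    fvals <- fx_s[sel[, 1] + dim(fixed$grid)[1] * (sel[, 2] - 1) +
                    prod(dim(fixed$grid)[1:2]) * (sel[, 3] - 1)]
    obj <- obj_factory(pts_world, fvals)
    fit <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = s$maxit, reltol = 1e-10))
    # restart to escape simplex collapse
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = s$maxit, reltol = 1e-10))
    par <- fit$par
    conv <- conv && fit$convergence == 0L
  }
  if (!conv) {
    warning("voxel registration did not fully converge within the iteration budget; returning best-so-far",
            call. = FALSE)
  }
  out <- rt_invert(rt_from_params(par[1:3], par[4:6], cfix))
  attr(out, "metric") <- 1 - fit$value
  attr(out, "converged") <- conv
  out
}

# recover optimiser parameters from a transform (inverse direction, centre c)
params_from_rt <- function(t_inv, center) {
  R <- t_inv$rotation
  # intrinsic XYZ Euler: R = Rz Ry Rx
  ry <- asin(max(-1, min(1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  trans <- t_inv$translation - (center - as.numeric(R %*% center))
  c(rx, ry, rz) * 180 / pi -> angs
  c(angs, trans)
}
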