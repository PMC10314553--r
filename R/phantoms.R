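#' Synthetic airway phantom with analytic ground truth
#'
#' Voxelizes a vertical tube (constant or piecewise-constant radius) on an
#' isotropic grid and places the airway landmarks so that every delimited
#' region has a closed-form volume and lateral surface area. The tube axis
#' runs along +Z through `(0, 0)`; `Ba` and `PNS` sit on the (optionally
#' tilted) base plane, `C2I`/`C4S` on the axis at their levels, and head
#' orientation landmarks are included so phantom data flow through the full
#' pipeline. The tube extends beyond the outer planes so that the
#' artificial end caps never intersect the measured slabs.
#'
#' The voxel lattice is placed with the tube axis at a quarter-voxel offset
#' from the voxel centres: centring the axis exactly on a voxel centre is a
#' lattice-degenerate alignment (many voxel centres fall exactly on the rim
#' of the cross-section circle, biasing the digitized area), while a generic
#' offset keeps in-plane digitization error near its typical small value.
#'
#' @param radius tube radius (mm), used when `radius_profile` is `NULL`.
#' @param levels named numeric: `base`, `c2i`, `c4s` axis heights (mm),
#'   strictly decreasing.
#' @param tilt_deg base/C2I/C4S plane tilt about +X (degrees); requires a
#'   constant radius.
#' @param spacing isotropic voxel size (mm), e.g. 0.4 as in CBCT protocols.
#' @param radius_profile optional piecewise-constant radius: a list with
#'   `breaks` (length m+1 increasing z) and `radius` (length m); overrides
#'   `radius` inside the break range.
#' @param markers optional list of spheres (`list(center=, radius=)`) merged
#'   into the mask to break rotational symmetry for registration tests;
#'   analytic ground truth is only valid for the marker-free tube.
#' @param margin z extension of the tube beyond the outer planes (mm).
#' @param z_extent optional explicit tube extent `c(lo, hi)` (mm); the
#'   landmark levels must fall strictly inside it. Default: derived from the
#'   levels plus `margin`.
#' @param motion optional [rigid_transform()] applied to the whole object
#'   (anatomy + landmarks) before voxelization, emulating a second scan of
#'   moved anatomy: the mask is voxelized analytically in the moved pose
#'   (no resampling), which gives registration tests an exact ground truth.
#' @param patient_id,timepoint identifiers for the landmark set.
#' @return A list with `mask` ([voxel_mask()]), `landmarks`
#'   ([landmark_set()]) and `truth` (an `airway_measurement` tibble of the
#'   analytic region volumes/lateral areas).
#' @export
make_airway_phantom <- function(radius = 10,
                                levels = c(base = 40, c2i = 15, c4s = -10),
                                tilt_deg = 0, spacing = 0.4,
                                radius_profile = NULL, markers = NULL,
                                margin = 5, z_extent = NULL, motion = NULL,
                                patient_id = "phantom", timepoint = "T0") {
  stopifnot(spacing > 0)
  lv <- c(levels[["base"]], levels[["c2i"]], levels[["c4s"]])
  if (!(lv[1] > lv[2] && lv[2] > lv[3])) {
    stop("landmark levels must be strictly ordered base > c2i > c4s", call. = FALSE)
  }
  if (!is.null(radius_profile) && tilt_deg != 0) {
    stop("tilted planes require a constant radius (analytic truth)", call. = FALSE)
  }
  r_of_z <- function(z) {
    if (is.null(radius_profile)) return(rep(radius, length(z)))
    r <- rep(radius, length(z))
    br <- radius_profile$breaks; rr <- radius_profile$radius
    for (i in seq_along(rr)) r[z >= br[i] & z < br[i + 1]] <- rr[i]
    r
  }
  rmax <- if (is.null(radius_profile)) radius else max(radius, radius_profile$radius)
  tilt_allow <- abs(tan(tilt_deg * pi / 180)) * (rmax + 2)
  if (is.null(z_extent)) {
    z_lo <- lv[3] - margin - tilt_allow   # tube extent
    z_hi <- lv[1] + margin + tilt_allow
  } else {
    z_lo <- z_extent[1]; z_hi <- z_extent[2]
  }
  gx_half <- rmax + 2                   # grid extent (grows with markers)
  gz_lo <- z_lo; gz_hi <- z_hi
  if (!is.null(markers)) {
    for (mk in markers) {
      gx_half <- max(gx_half, abs(mk$center[1]) + mk$radius + 2,
                     abs(mk$center[2]) + mk$radius + 2)
      gz_lo <- min(gz_lo, mk$center[3] - mk$radius - 2)
      gz_hi <- max(gz_hi, mk$center[3] + mk$radius + 2)
    }
  }
  if (z_lo >= lv[3] || z_hi <= lv[1]) stop("levels outside the tube z-extent", call. = FALSE)

  # voxel-centre lattice with quarter-voxel offset from the axis
  centers_1d <- function(lo, hi) {
    k <- seq(floor(lo / spacing) - 1, ceiling(hi / spacing) + 1)
    (k + 0.25) * spacing
  }
  # world-frame bounds: object-frame box, swept through the motion if any
  bounds <- rbind(c(-gx_half, gx_half), c(-gx_half, gx_half), c(gz_lo, gz_hi))
  if (!is.null(motion)) {
    corners <- as.matrix(expand.grid(bounds[1, ], bounds[2, ], bounds[3, ]))
    moved <- rt_apply(motion, corners)
    bounds <- t(apply(moved, 2, range))
  }
  xs <- centers_1d(bounds[1, 1], bounds[1, 2])
  ys <- centers_1d(bounds[2, 1], bounds[2, 2])
  zs <- centers_1d(bounds[3, 1], bounds[3, 2])
  nx <- length(xs); ny <- length(ys); nz <- length(zs)

  indicator <- function(pts) {
    rz <- r_of_z(pts[, 3])
    inside <- (pts[, 1]^2 + pts[, 2]^2 <= rz^2) &
      pts[, 3] >= z_lo & pts[, 3] <= z_hi
    if (!is.null(markers)) {
      for (mk in markers) {
        inside <- inside |
          ((pts[, 1] - mk$center[1])^2 + (pts[, 2] - mk$center[2])^2 +
             (pts[, 3] - mk$center[3])^2 <= mk$radius^2)
      }
    }
    inside
  }
  if (is.null(motion)) {
    # fast separable path: per-slice disc test
    rz <- r_of_z(zs)
    in_z <- zs >= z_lo & zs <= z_hi
    r2xy <- outer(xs^2, ys^2, "+")
    grid <- array(0L, c(nx, ny, nz))
    for (k in seq_len(nz)) {
      if (in_z[k]) grid[, , k] <- as.integer(r2xy <= rz[k]^2)
    }
    if (!is.null(markers)) {
      for (mk in markers) {
        d2 <- outer(outer((xs - mk$center[1])^2, (ys - mk$center[2])^2, "+"),
                    (zs - mk$center[3])^2, "+")
        grid <- array(as.integer(grid | (d2 <= mk$radius^2)), c(nx, ny, nz))
      }
    }
  } else {
    pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    obj_pts <- rt_apply(rt_invert(motion), pts)
    grid <- array(as.integer(indicator(obj_pts)), c(nx, ny, nz))
  }
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(rep(spacing, 3))
  affine[1:3, 4] <- c(xs[1], ys[1], zs[1]) - spacing
  mask <- voxel_mask(grid, affine)

  tb <- tan(tilt_deg * pi / 180)
  yoff <- rmax + 2
  lm <- landmark_set(rbind(
    Ba = c(0, -yoff, lv[1] - tb * yoff),
    PNS = c(0, yoff, lv[1] + tb * yoff),
    C2I = c(0, 0, lv[2]),
    C4S = c(0, 0, lv[3]),
    PoR = c(-60, 0, lv[1] + 15), PoL = c(60, 0, lv[1] + 15),
    OrR = c(-30, 70, lv[1] + 15), OrL = c(30, 70, lv[1] + 15)),
    frame = "oriented", patient_id = patient_id, timepoint = timepoint)
  if (!is.null(motion)) lm <- apply_transform(lm, motion, frame = "scanner")

  truth <- analytic_tube_measurement(radius, lv, radius_profile, patient_id, timepoint)
  list(mask = mask, landmarks = lm, truth = truth)
}

# closed-form region volumes and lateral areas of the (possibly piecewise)
# tube between parallel planes passing through axis heights lv; tilt about X
# leaves both invariant (shear symmetry), so only axis heights matter.
analytic_tube_measurement <- function(radius, lv, radius_profile, patient_id, timepoint) {
  seg <- function(z_hi, z_lo) {
    if (is.null(radius_profile)) {
      h <- z_hi - z_lo
      return(c(vol = pi * radius^2 * h, area = 2 * pi * radius * h))
    }
    br <- radius_profile$breaks; rr <- radius_profile$radius
    vol <- 0; area <- 0
    pieces_lo <- c(-Inf, br, Inf)
    pieces_r <- c(radius, radius_profile$radius, radius)
    # piece i spans [pieces_lo[i], pieces_lo[i+1]) with radius pieces_r[i]
    for (i in seq_along(pieces_r)) {
      lo <- max(z_lo, pieces_lo[i]); hi <- min(z_hi, pieces_lo[i + 1])
      if (hi > lo) {
        vol <- vol + pi * pieces_r[i]^2 * (hi - lo)
        area <- area + 2 * pi * pieces_r[i] * (hi - lo)
      }
    }
    # annular steps at interior breaks inside the slab
    for (i in seq_along(pieces_r)[-1]) {
      zb <- pieces_lo[i]
      if (zb > z_lo && zb < z_hi) {
        area <- area + pi * abs(pieces_r[i]^2 - pieces_r[i - 1]^2)
      }
    }
    c(vol = vol, area = area)
  }
  sup <- seg(lv[1], lv[2]); inf <- seg(lv[2], lv[3])
  out <- tibble::tibble(
    patient_id = patient_id, timepoint = timepoint,
    total_volume = sup[["vol"]] + inf[["vol"]],
    superior_volume = sup[["vol"]], inferior_volume = inf[["vol"]],
    total_area = sup[["area"]] + inf[["area"]],
    superior_area = sup[["area"]], inferior_area = inf[["area"]])
  class(out) <- c("airway_measurement", class(out))
  out
}

default_mandible_template <- function() {
  rbind(CoR = c(50, -10, 0), CoL = c(-50, -10, 0),
        GoR = c(45, -5, -40), GoL = c(-45, -5, -40),
        B = c(0, 45, -55))
}

#' Synthetic mandibular motion case with known kinematics
#'
#' Applies a programmed rigid motion -- pitch about the +X axis through the
#' mid-condylar point plus an anteroposterior/superoinferior translation --
#' to a T0 landmark template, returning both landmark sets and the implied
#' ground-truth change record (all four pitch measures equal the programmed
#' angle; the displacement is the actual B-point image minus B).
#'
#' @param pitch_deg programmed pitch (degrees; + = counterclockwise from the
#'   patient's right).
#' @param translation length-2 numeric `c(ap, si)` translation (mm).
#' @param template n x 3 landmark matrix with rownames `CoR`, `CoL`, `GoR`,
#'   `GoL`, `B` (default: realistic mandibular geometry).
#' @param patient_id identifier.
#' @return A list with `t0`, `t1` ([landmark_set()]) and `truth` (a
#'   `mandible_change` tibble).
#' @export
make_mandible_case <- function(pitch_deg = 0, translation = c(0, 0),
                               template = default_mandible_template(),
                               patient_id = "phantom") {
  need <- c("CoR", "CoL", "GoR", "GoL", "B")
  stopifnot(all(need %in% rownames(template)))
  center <- colMeans(template[c("CoR", "CoL"), , drop = FALSE])
  motion <- rt_compose(
    rigid_transform(diag(3), c(0, translation[1], translation[2])),
    rt_axis_rotation(pitch_deg, "x", center = center))
  t0 <- landmark_set(template, frame = "oriented", patient_id = patient_id,
                     timepoint = "T0")
  t1 <- apply_transform(t0, motion)
  t1$timepoint <- "T1"
  b0 <- lm_get(t0, "B"); b1 <- lm_get(t1, "B")
  truth <- tibble::tibble(
    patient_id = patient_id,
    delta_ap = b1[["y"]] - b0[["y"]], delta_si = b1[["z"]] - b0[["z"]],
    ramus_pitch_R = pitch_deg, ramus_pitch_L = pitch_deg,
    anterior_pitch_R = pitch_deg, anterior_pitch_L = pitch_deg,
    ramus_pitch_mean = pitch_deg, anterior_pitch_mean = pitch_deg,
    sign_convention = "+ = counterclockwise from patient right (anterior up)")
  class(truth) <- c("mandible_change", class(truth))
  list(t0 = t0, t1 = t1, truth = truth, motion = motion)
}

#' Repeated landmarkings with Gaussian jitter
#'
#' Emulates intra-rater repeated landmark placement: each repeat displaces
#' every landmark by an independent isotropic Gaussian error.
#'
#' @param lm A [landmark_set()].
#' @param sigma per-coordinate jitter SD (mm), `>= 0`.
#' @param n_repeats number of repeated sets.
#' @param seed RNG seed; the same seed reproduces identical repeats.
#' @return List of `n_repeats` jittered [landmark_set()]s.
#' @export
jitter_landmarks <- function(lm, sigma, n_repeats, seed = 1L) {
  stopifnot(sigma >= 0, n_repeats >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  lapply(seq_len(n_repeats), function(i) {
    jit <- matrix(stats::rnorm(length(lm$points), sd = sigma), nrow(lm$points), 3)
    out <- lm
    out$points <- lm$points + jit
    out
  })
}

#' Default two-group cohort specification
#'
#' Per-group, per-variable baseline and change distributions at the scale of
#' the study cohort (oral-appliance vs two-jaw-surgery groups, n = 17 each),
#' plus inter-variable correlation targets for the change scores. Change
#' SDs of the airway variables are derived from the baseline/follow-up SDs
#' assuming a within-subject T0-T1 correlation of 0.8. The correlation
#' fill-in values keep the target matrix positive definite.
#'
#' @param n_per_group patients per group.
#' @return A list of class `cohort_spec` with elements `n_per_group`,
#'   `variables` (tibble) and `correlations` (named list of matrices).
#' @export
cohort_spec <- function(n_per_group = 17) {
  rho_t <- 0.8
  chg_sd <- function(s0, s1) sqrt(s0^2 + s1^2 - 2 * rho_t * s0 * s1)
  airway <- tibble::tribble(
    ~variable,          ~group, ~t0_mean, ~t0_sd, ~t1_mean, ~t1_sd,
    "total_volume",     "MAD", 12860.12, 4442.52, 14130.82, 4258.66,
    "total_volume",     "MMA", 13485.22, 8376.86, 19984.25, 8906.67,
    "total_area",       "MAD", 5380.06, 1245.42, 5685.71, 1297.52,
    "total_area",       "MMA", 5153.73, 1790.80, 6662.65, 1992.15,
    "superior_volume",  "MAD", 7993.69, 2397.96, 10049.33, 3555.98,
    "superior_volume",  "MMA", 10030.88, 6559.56, 15248.59, 6946.79,
    "superior_area",    "MAD", 3440.90, 736.27, 3836.44, 860.38,
    "superior_area",    "MMA", 3780.54, 1665.06, 5100.30, 1821.71,
    "inferior_volume",  "MAD", 4863.08, 2382.66, 4311.76, 2267.63,
    "inferior_volume",  "MMA", 4105.69, 2019.74, 6183.29, 2338.97,
    "inferior_area",    "MAD", 2279.50, 722.15, 2082.07, 707.66,
    "inferior_area",    "MMA", 2034.82, 515.63, 2731.81, 709.37)
  airway$change_mean <- airway$t1_mean - airway$t0_mean
  airway$change_sd <- chg_sd(airway$t0_sd, airway$t1_sd)
  mand <- tibble::tribble(
    ~variable,             ~group, ~change_mean, ~change_sd,
    "delta_ap",            "MAD", 2.75, 3.08,
    "delta_ap",            "MMA", 6.47, 4.67,
    "delta_si",            "MAD", -9.29, 3.06,
    "delta_si",            "MMA", 1.66, 4.32,
    "ramus_pitch_mean",    "MAD", -3.97, 1.07,
    "ramus_pitch_mean",    "MMA", 2.40, 3.43,
    "anterior_pitch_mean", "MAD", -4.08, 1.30,
    "anterior_pitch_mean", "MMA", 3.41, 2.79)
  mand$t0_mean <- NA_real_; mand$t0_sd <- NA_real_
  mand$t1_mean <- NA_real_; mand$t1_sd <- NA_real_
  variables <- dplyr::bind_rows(airway, mand)

  vn <- unique(variables$variable)
  corr <- list(MAD = diag(length(vn)), MMA = diag(length(vn)))
  dimnames(corr$MAD) <- dimnames(corr$MMA) <- list(vn, vn)
  set_r <- function(g, a, b, r) {
    corr[[g]][a, b] <<- r; corr[[g]][b, a] <<- r
  }
  # printed significant correlations of the study, plus positive-definite
  # fill-ins for the pairs the study does not print
  set_r("MAD", "delta_ap", "superior_volume", -0.697)
  set_r("MAD", "delta_ap", "inferior_volume", 0.658)
  set_r("MAD", "delta_si", "anterior_pitch_mean", 0.557)
  set_r("MMA", "delta_ap", "superior_volume", -0.530)
  set_r("MMA", "delta_si", "superior_volume", 0.488)
  set_r("MMA", "delta_ap", "ramus_pitch_mean", 0.743)
  set_r("MMA", "delta_ap", "anterior_pitch_mean", 0.785)
  set_r("MMA", "delta_si", "anterior_pitch_mean", 0.753)
  set_r("MMA", "delta_ap", "delta_si", 0.35)
  set_r("MMA", "ramus_pitch_mean", "anterior_pitch_mean", 0.85)
  set_r("MMA", "delta_si", "ramus_pitch_mean", 0.60)
  set_r("MAD", "ramus_pitch_mean", "anterior_pitch_mean", 0.70)

  structure(list(n_per_group = n_per_group, variables = variables,
                 correlations = corr),
            class = "cohort_spec")
}

#' Simulate a two-group treatment cohort
#'
#' Draws per-patient baseline values and change scores from the cohort
#' specification: changes are multivariate normal honouring the per-group
#' correlation targets, follow-up = baseline + change, demographics follow
#' the study's printed group distributions (age, weight, height; BMI derived
#' from weight/height; sex at the printed group ratios; AHI only for the
#' appliance group, which is the one with sleep-study data).
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return A list with `manifest` (cohort manifest tibble) and
#'   `measurements` (wide per-patient table: `<airway var>_t0/_t1` plus
#'   mandible change columns), both carrying the seed as an attribute.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (g in names(spec$correlations)) {
    ev <- eigen(spec$correlations[[g]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      stop(sprintf("correlation target for group %s is not positive definite", g),
           call. = FALSE)
    }
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- spec$n_per_group
  demo <- list(
    MAD = list(age = c(47.35, 9.33), weight = c(70.76, 16.01),
               height = c(1.65, 0.13), n_male = round(n * 9 / 17)),
    MMA = list(age = c(34.00, 11.20), weight = c(68.59, 15.89),
               height = c(1.67, 0.11), n_male = round(n * 7 / 17)))

  rows_manifest <- list(); rows_meas <- list()
  for (g in c("MAD", "MMA")) {
    vars <- spec$variables[spec$variables$group == g, ]
    vn <- vars$variable
    corr <- spec$correlations[[g]][vn, vn]
    D <- diag(vars$change_sd)
    changes <- MASS::mvrnorm(n, mu = vars$change_mean, Sigma = D %*% corr %*% D)
    colnames(changes) <- vn

    d <- demo[[g]]
    age <- stats::rnorm(n, d$age[1], d$age[2])
    weight <- pmax(40, stats::rnorm(n, d$weight[1], d$weight[2]))
    height <- pmax(1.4, stats::rnorm(n, d$height[1], d$height[2]))
    sex <- sample(c(rep("M", d$n_male), rep("F", n - d$n_male)))
    if (g == "MAD") {
      ahi_t0 <- pmin(80, pmax(5, stats::rlnorm(n, log(28), 0.45)))
      ahi_t1 <- ahi_t0 * stats::runif(n, 0.1, 0.55)
    } else {
      ahi_t0 <- rep(NA_real_, n); ahi_t1 <- rep(NA_real_, n)
    }
    pid <- sprintf("%s%02d", g, seq_len(n))
    rows_manifest[[g]] <- tibble::tibble(
      patient_id = pid, group = g, sex = sex,
      age = age, weight = weight, height = height, bmi = weight / height^2,
      ahi_t0 = ahi_t0, ahi_t1 = ahi_t1)

    meas <- tibble::tibble(patient_id = pid, group = g)
    for (i in seq_along(vn)) {
      v <- vn[i]
      if (!is.na(vars$t0_mean[i])) {
        t0 <- stats::rnorm(n, vars$t0_mean[i], vars$t0_sd[i])
        meas[[paste0(v, "_t0")]] <- t0
        meas[[paste0(v, "_t1")]] <- t0 + changes[, v]
      } else {
        meas[[v]] <- changes[, v]
      }
    }
    rows_meas[[g]] <- meas
  }
  manifest <- dplyr::bind_rows(rows_manifest)
  measurements <- dplyr::bind_rows(rows_meas)
  attr(manifest, "seed") <- as.integer(seed)
  attr(measurements, "seed") <- as.integer(seed)
  list(manifest = manifest, measurements = measurements)
}
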