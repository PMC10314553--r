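test_that("phantom generation is deterministic and validates its spec", {
  a <- make_airway_phantom(radius = 8, spacing = 1)
  b <- make_airway_phantom(radius = 8, spacing = 1)
  expect_identical(a$mask$grid, b$mask$grid)
  expect_identical(a$landmarks$points, b$landmarks$points)
  expect_error(make_airway_phantom(levels = c(base = 10, c2i = 20, c4s = -10)),
               "strictly ordered")
  expect_error(make_airway_phantom(levels = c(base = 40, c2i = 15, c4s = -10),
                                   z_extent = c(-20, 30)),
               "z-extent")
})

test_that("phantom ground truth closes with the measurement pipeline", {
  ph <- make_airway_phantom(radius = 10, levels = c(base = 40, c2i = 15, c4s = -10),
                            spacing = 0.4)
  expect_equal(ph$truth$superior_volume, pi * 100 * 25)
  expect_equal(ph$truth$total_area, 2 * pi * 10 * 50)
  m <- measure_airway(ph$mask, ph$landmarks)
  for (v in c("total_volume", "superior_volume", "inferior_volume")) {
    expect_rel_error(m[[v]], ph$truth[[v]], 0.01)
  }
  for (v in c("total_area", "superior_area", "inferior_area")) {
    expect_rel_error(m[[v]], ph$truth[[v]], 0.03)
  }
})

test_that("piecewise radius profiles get closed-form truth including step annuli", {
  prof <- list(breaks = c(15, 40), radius = 7)   # narrower superior segment
  ph <- make_airway_phantom(radius = 10, radius_profile = prof, spacing = 0.5)
  expect_equal(ph$truth$superior_volume, pi * 49 * 25)
  expect_equal(ph$truth$inferior_volume, pi * 100 * 25)
  # superior slab contains no step annulus (steps sit exactly at the planes,
  # which belong to the region above); lateral truth is per-segment
  expect_equal(ph$truth$superior_area, 2 * pi * 7 * 25)
  m <- measure_airway(ph$mask, ph$landmarks)
  expect_rel_error(m$superior_volume, ph$truth$superior_volume, 0.01)
  expect_rel_error(m$inferior_volume, ph$truth$inferior_volume, 0.01)
})

test_that("coarser voxels give larger mean volume error on the same phantom", {
  set.seed(41)
  err_at <- function(sp) {
    mean(vapply(1:4, function(i) {
      ph <- make_airway_phantom(radius = 10,
                                levels = c(base = 40, c2i = 15.7, c4s = -10),
                                spacing = sp,
                                motion = rigid_transform(diag(3), runif(3, 0, sp)))
      pl <- build_delimiting_planes(ph$landmarks)
      v <- region_volume(ph$mask, pl$base, pl$c2i)
      abs(v / ph$truth$superior_volume - 1)
    }, numeric(1)))
  }
  expect_gt(err_at(1.0), err_at(0.4))
})

test_that("landmark jitter has the requested spread and is seed-reproducible", {
  lm <- make_airway_phantom(radius = 8, spacing = 1)$landmarks
  expect_identical(jitter_landmarks(lm, 0, 3, seed = 5)[[2]]$points, lm$points)

  reps <- jitter_landmarks(lm, 0.3, 200, seed = 5)
  dev <- vapply(reps, function(l) l$points["C2I", "z"] - lm$points["C2I", "z"],
                numeric(1))
  expect_gt(sd(dev), 0.27)
  expect_lt(sd(dev), 0.33)

  again <- jitter_landmarks(lm, 0.3, 200, seed = 5)
  expect_identical(vapply(again, function(l) l$points["C2I", "z"], numeric(1)),
                   vapply(reps, function(l) l$points["C2I", "z"], numeric(1)))
})

test_that("mandible cases reproduce their programmed kinematics exactly", {
  mad <- make_mandible_case(pitch_deg = -4, translation = c(2.75, -9.29))
  m <- measure_mandible(mad$t0, mad$t1)
  for (v in c("ramus_pitch_R", "ramus_pitch_L", "anterior_pitch_R",
              "anterior_pitch_L", "delta_ap", "delta_si")) {
    expect_equal(m[[v]], mad$truth[[v]], tolerance = 1e-6)
  }
  idm <- make_mandible_case()
  expect_equal(unlist(idm$truth[, 2:9], use.names = FALSE), rep(0, 8))
  mma <- make_mandible_case(pitch_deg = 3.41)
  expect_true(all(unlist(mma$truth[, 4:9]) > 0))
})

test_that("cohort simulation is deterministic, typed and correlation-aware", {
  spec <- cohort_spec(n_per_group = 17)
  a <- simulate_cohort(spec, seed = 3)
  b <- simulate_cohort(spec, seed = 3)
  expect_identical(a$measurements, b$measurements)
  expect_identical(nrow(a$manifest), 34L)
  expect_identical(as.integer(table(a$manifest$group)[c("MAD", "MMA")]),
                   c(17L, 17L))
  expect_true(all(c("total_volume_t0", "total_volume_t1", "delta_ap",
                    "ramus_pitch_mean") %in% names(a$measurements)))
  # only the appliance group carries sleep-study data
  expect_true(all(is.na(a$manifest$ahi_t0[a$manifest$group == "MMA"])))
  expect_true(all(!is.na(a$manifest$ahi_t0[a$manifest$group == "MAD"])))

  bad <- spec
  bad$correlations$MAD["delta_ap", "delta_si"] <- 0.999
  bad$correlations$MAD["delta_si", "delta_ap"] <- 0.999
  expect_error(simulate_cohort(bad, seed = 1), "not positive definite")
})

test_that("programmed correlations and effects are recovered across seeds", {
  spec <- cohort_spec(n_per_group = 17)
  stats_by_seed <- vapply(1:300, function(s) {
    m <- simulate_cohort(spec, seed = s)$measurements
    sel <- m$group == "MAD"
    dv <- m$superior_volume_t1[sel] - m$superior_volume_t0[sel]
    c(r = cor(m$delta_ap[sel], dv),
      rej = paired_t(m$inferior_volume_t0[!sel],
                     m$inferior_volume_t1[!sel])$p_two_sided < 0.05)
  }, numeric(2))
  expect_gt(mean(stats_by_seed["r", ]), -0.75)
  expect_lt(mean(stats_by_seed["r", ]), -0.65)
  # the surgical group's programmed inferior-volume gain is detected
  expect_gt(mean(stats_by_seed["rej", ]), 0.95)
})

test_that("null cohorts give nominal paired-t rejection", {
  spec <- cohort_spec(n_per_group = 17)
  spec$variables$change_mean <- 0
  rej <- vapply(1:400, function(s) {
    m <- simulate_cohort(spec, seed = s)$measurements
    sel <- m$group == "MAD"
    paired_t(m$total_volume_t0[sel], m$total_volume_t1[sel])$p_two_sided < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
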