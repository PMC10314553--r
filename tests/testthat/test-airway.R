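airway_lm <- function(ba = c(0, -40, 40), pns = c(0, 10, 40),
                      c2i = c(0, 0, 15), c4s = c(0, 0, -10)) {
  landmark_set(rbind(Ba = ba, PNS = pns, C2I = c2i, C4S = c4s))
}

test_that("delimiting planes: horizontal, oblique and degenerate cases", {
  pl <- build_delimiting_planes(airway_lm())
  expect_equal(pl$normal, c(0, 0, 1))
  expect_equal(pl$base$offset, 40)

  # oblique Ba-PNS: normal is the in-sagittal perpendicular, superior positive
  pl2 <- build_delimiting_planes(airway_lm(ba = c(0, -40, 44), pns = c(0, 10, 36)))
  expect_equal(pl2$normal, c(0, 8, 50) / sqrt(64 + 2500), tolerance = 1e-12)
  # the base plane contains both defining landmarks
  expect_equal(sum(pl2$normal * c(0, -40, 44)), pl2$base$offset, tolerance = 1e-9)
  expect_equal(sum(pl2$normal * c(0, 10, 36)), pl2$base$offset, tolerance = 1e-9)

  expect_error(build_delimiting_planes(airway_lm(pns = c(0, -40, 40))), "coincide")
  expect_error(build_delimiting_planes(airway_lm(c2i = c(0, 0, -10), c4s = c(0, 0, 15))),
               "ordering violated")
})

test_that("region volume: full-grid arithmetic and parallel-plane validation", {
  m <- small_box_mask(spacing = 0.5, n = 20)  # 20^3 x 0.125 mm^3 = 1000 mm^3
  up <- airway_plane(c(0, 0, 100), c(0, 0, 1))
  lo <- airway_plane(c(0, 0, -100), c(0, 0, 1))
  expect_equal(region_volume(m, up, lo), 1000)
  tilted <- airway_plane(c(0, 0, -100), c(0, 0.3, 1))
  expect_error(region_volume(m, up, tilted), "not parallel")
  expect_error(region_volume(m, lo, up), "strictly superior")
})

test_that("cylinder volumes match the analytic value within 1% (and 1.5% tilted)", {
  ph <- make_airway_phantom(radius = 10, levels = c(base = 40, c2i = 15, c4s = -10),
                            spacing = 0.4)
  m <- measure_airway(ph$mask, ph$landmarks)
  expect_rel_error(m$total_volume, pi * 100 * 50, 0.01)
  expect_rel_error(m$superior_volume, pi * 100 * 25, 0.01)
  expect_rel_error(m$inferior_volume, pi * 100 * 25, 0.01)

  ph10 <- make_airway_phantom(radius = 10, tilt_deg = 10, spacing = 0.4)
  m10 <- measure_airway(ph10$mask, ph10$landmarks)
  expect_rel_error(m10$total_volume, ph10$truth$total_volume, 0.015)
  expect_rel_error(m10$superior_volume, ph10$truth$superior_volume, 0.015)
  expect_rel_error(m10$inferior_volume, ph10$truth$inferior_volume, 0.015)
})

test_that("lateral surface areas match 2*pi*r*h within 3% and exclude caps", {
  ph <- make_airway_phantom(radius = 10, spacing = 0.4)
  m <- measure_airway(ph$mask, ph$landmarks)
  expect_rel_error(m$total_area, 2 * pi * 10 * 50, 0.03)
  expect_rel_error(m$superior_area, 2 * pi * 10 * 25, 0.03)
  expect_rel_error(m$inferior_area, 2 * pi * 10 * 25, 0.03)
  # cap exclusion: measured total well below lateral + two cap discs
  expect_lt(m$total_area, 2 * pi * 10 * 50 + pi * 100)
})

test_that("empty slab gives zero area and adjacent slabs partition the surface", {
  ph <- make_airway_phantom(radius = 10, spacing = 0.5)
  surf <- mask_surface(ph$mask)
  n <- c(0, 0, 1)
  plane_at <- function(z) airway_plane(c(0, 0, z), n)
  empty <- region_surface_area(ph$mask, plane_at(2000), plane_at(1000), surface = surf)
  expect_identical(empty, 0)
  whole <- region_surface_area(ph$mask, plane_at(40), plane_at(-10), surface = surf)
  sup <- region_surface_area(ph$mask, plane_at(40), plane_at(15), surface = surf)
  inf <- region_surface_area(ph$mask, plane_at(15), plane_at(-10), surface = surf)
  expect_equal(sup + inf, whole, tolerance = 0.005)
})

test_that("superior + inferior volume equals total exactly for arbitrary geometry", {
  set.seed(20)
  ph <- make_airway_phantom(radius = 9, spacing = 0.8)
  for (i in 1:6) {
    lm <- airway_lm(ba = c(0, -40, 40 + runif(1, -3, 3)),
                    pns = c(0, 10, 40 + runif(1, -6, 6)),
                    c2i = c(runif(1, -2, 2), runif(1, -2, 2), runif(1, 10, 20)),
                    c4s = c(runif(1, -2, 2), runif(1, -2, 2), runif(1, -14, -6)))
    m <- suppressWarnings(measure_airway(ph$mask, lm))
    expect_identical(m$superior_volume + m$inferior_volume, m$total_volume)
    expect_true(all(unlist(m[, 3:8]) >= 0))
  }
})

test_that("a mask entirely outside the delimited region warns and returns zeros", {
  ph <- make_airway_phantom(radius = 8, spacing = 1)
  lm <- airway_lm(ba = c(0, -40, -200), pns = c(0, 10, -200),
                  c2i = c(0, 0, -225), c4s = c(0, 0, -250))
  expect_warning(m <- measure_airway(ph$mask, lm), "does not intersect")
  expect_equal(unlist(m[, 3:8], use.names = FALSE), rep(0, 6))
})

test_that("volumes and areas are rigid-invariant within 0.5%", {
  ph <- make_airway_phantom(radius = 10, spacing = 0.5)
  m0 <- measure_airway(ph$mask, ph$landmarks)
  common <- rt_compose(rigid_transform(diag(3), c(4.3, -2.7, 1.9)),
                       rt_from_params(c(5, -3, 7), center = c(0, 0, 15)))
  # analytic re-voxelization in the moved pose (a rigid motion of the anatomy)
  moved <- make_airway_phantom(radius = 10, spacing = 0.5, motion = common)
  m1 <- measure_airway(moved$mask, moved$landmarks)
  for (v in c("total_volume", "superior_volume", "inferior_volume",
              "total_area", "superior_area", "inferior_area")) {
    expect_lt(abs(m1[[v]] / m0[[v]] - 1), 0.005)
  }
})

test_that("mean digitization error of region volume shrinks with voxel size", {
  # region heights chosen away from exact voxel multiples so the slab-height
  # quantisation also averages over the seeded random placements
  set.seed(77)
  spacings <- c(1.0, 0.8, 0.6, 0.4)
  mean_err <- vapply(spacings, function(sp) {
    errs <- vapply(1:12, function(i) {
      shift <- rigid_transform(diag(3), runif(3, 0, sp))
      ph <- make_airway_phantom(radius = 10,
                                levels = c(base = 40, c2i = 15.7, c4s = -10),
                                spacing = sp, motion = shift)
      pl <- build_delimiting_planes(ph$landmarks)
      v <- region_volume(ph$mask, pl$base, pl$c2i)
      abs(v / ph$truth$superior_volume - 1)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
})
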