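test_that("read_mask binarizes, reports volume, and rejects empty segmentations", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ones.nii.gz")
  img <- RNifti::asNifti(array(1L, c(10, 10, 10)))
  aff <- diag(c(0.4, 0.4, 0.4, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, p)
  m <- read_mask(p)
  expect_s3_class(m, "voxel_mask")
  expect_equal(mask_volume(m), 64, tolerance = 1e-6)  # 1000 voxels x 0.064 mm^3
  expect_equal(m$spacing, rep(0.4, 3), tolerance = 1e-6)

  pz <- file.path(dir, "zeros.nii.gz")
  img0 <- RNifti::asNifti(array(0L, c(5, 5, 5)))
  RNifti::writeNifti(img0, pz)
  expect_error(read_mask(pz), "empty segmentation")
  expect_error(read_mask(file.path(dir, "nope.nii")), "not found")
})

test_that("LPS-headed NIfTI reorients to the same world geometry as RAS", {
  dir <- withr::local_tempdir()
  a <- array(0L, c(10, 12, 14)); a[2, 3, 4] <- 1L
  # LPS-oriented header: negative x/y axes
  lps <- RNifti::asNifti(a)
  m_lps <- diag(c(-0.4, -0.4, 0.4, 1)); m_lps[1:3, 4] <- c(2, 3, -1)
  RNifti::sform(lps) <- structure(m_lps, code = 2L)
  p1 <- file.path(dir, "lps.nii.gz"); RNifti::writeNifti(lps, p1)
  mask <- read_mask(p1)
  # world position of the single voxel, via the original 0-based LPS affine
  expected <- (m_lps %*% c(1, 2, 3, 1))[1:3]
  got <- voxel_world(mask)
  expect_equal(as.numeric(got), as.numeric(expected), tolerance = 1e-5)

  # idempotence under re-save: save -> load preserves grid and geometry
  p2 <- file.path(dir, "resaved.nii.gz")
  write_mask(mask, p2)
  mask2 <- read_mask(p2)
  expect_identical(mask2$grid, mask$grid)
  expect_equal(mask2$affine, mask$affine, tolerance = 1e-6)
})

test_that("FCSV honours the declared coordinate system and normalizes names", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "lm.fcsv")
  writeLines(c(
    "# Markups fiducial file version = 4.11",
    "# CoordinateSystem = LPS",
    "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
    "f1,-10,-20,30,0,0,0,1,1,1,0,Basion,,",
    "f2,0,40,40,0,0,0,1,1,1,0,PNS,,"), p)
  lm <- read_landmarks(p)
  expect_equal(unname(lm_get(lm, "Ba")), c(10, 20, 30))   # LPS -> RAS sign flip
  expect_equal(unname(lm_get(lm, "PNS")), c(0, -40, 40))

  # RAS dialect reads back identically
  p2 <- file.path(dir, "ras.fcsv")
  writeLines(c(
    "# Markups fiducial file version = 4.11",
    "# CoordinateSystem = RAS",
    "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
    "f1,0,-40,40,0,0,0,1,1,1,0,Ba,,"), p2)
  expect_equal(unname(lm_get(read_landmarks(p2), "Ba")), c(0, -40, 40))
})

test_that("the two fiducial dialects and write_landmarks round-trip identically", {
  dir <- withr::local_tempdir()
  lm <- landmark_set(rbind(Ba = c(1.5, -40.25, 40), C2I = c(0.125, 3, 15)))
  for (cs in c("RAS", "LPS")) {
    p <- file.path(dir, paste0(cs, ".fcsv"))
    write_landmarks(lm, p, coordinate_system = cs)
    back <- read_landmarks(p)
    expect_equal(back$points, lm$points, tolerance = 1e-9)
  }
})

test_that("markups JSON is read and missing task landmarks are listed", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "lm.mrk.json")
  obj <- list(markups = list(list(
    coordinateSystem = "LPS",
    controlPoints = list(
      list(label = "Ba", position = c(0, 40, 40)),
      list(label = "PNS", position = c(0, -10, 40))))))
  jsonlite::write_json(obj, p, auto_unbox = TRUE)
  expect_error(read_landmarks(p, task = "airway"), "C2I, C4S")
  lm <- read_landmarks(p)
  expect_equal(unname(lm_get(lm, "Ba")), c(0, -40, 40))
})

test_that("duplicate landmark labels are rejected", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "dup.fcsv")
  writeLines(c(
    "# Markups fiducial file version = 4.11",
    "# CoordinateSystem = 0",
    "f1,0,0,0,0,0,0,1,1,1,0,Ba,,",
    "f2,1,1,1,0,0,0,1,1,1,0,Basion,,"), p)
  expect_error(read_landmarks(p), "duplicate")
})

test_that("cohort manifest is typed, validated and counted", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "manifest.csv")
  df <- data.frame(
    patient_id = sprintf("P%02d", 1:34),
    group = rep(c("MAD", "MMA"), each = 17),
    sex = rep(c("M", "F"), 17),
    age = 40, weight = 70, height = 1.7, bmi = round(70 / 1.7^2, 1))
  utils::write.csv(df, p, row.names = FALSE)
  expect_message(man <- read_cohort_manifest(p), "MAD:17, MMA:17")
  expect_identical(nrow(man), 34L)

  df2 <- df; df2$bmi[1] <- 40
  utils::write.csv(df2, p, row.names = FALSE)
  expect_warning(read_cohort_manifest(p, quiet = TRUE), "24\\.2")

  df3 <- df; df3$patient_id[2] <- "P01"
  utils::write.csv(df3, p, row.names = FALSE)
  expect_error(read_cohort_manifest(p, quiet = TRUE), "duplicated patient_id")

  df4 <- df; df4$group[1] <- "CPAP"
  utils::write.csv(df4, p, row.names = FALSE)
  expect_error(read_cohort_manifest(p, quiet = TRUE), "unknown group")

  df5 <- df; df5$age <- as.character(df5$age); df5$age[3] <- "forty"
  utils::write.csv(df5, p, row.names = FALSE)
  expect_error(read_cohort_manifest(p, quiet = TRUE), "non-numeric")
})

test_that("measurement tables round-trip through CSV with NA preserved", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "meas.csv")
  rec <- tibble::tibble(patient_id = c("A", "B"),
                        total_volume = c(12860.123456789, 1 / 3),
                        total_area = c(NA_real_, 5380.06))
  write_measurements(rec, p)
  back <- read_measurements(p)
  expect_equal(back$total_volume, rec$total_volume, tolerance = 1e-12)
  expect_true(is.na(back$total_area[1]))
  expect_true(file.exists(sub("\\.csv$", ".json", p)))

  # empty record list -> header-only CSV
  write_measurements(rec[0, ], p)
  expect_identical(nrow(read_measurements(p)), 0L)
  expect_identical(names(read_measurements(p)), names(rec))
})
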