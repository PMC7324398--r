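test_that("volumes round-trip through disk with exact voxels and spacing", {
  set.seed(1)
  vol <- image_volume(array(rnorm(16 * 32 * 32), c(16, 32, 32)),
                      c(2.0, 0.5, 0.5), origin = c(1, 2, 3), "probe")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-5)
  expect_identical(dim(back), c(16L, 32L, 32L))

  zero <- image_volume(array(0, c(4, 5, 6)), c(1, 1, 1))
  f2 <- tempfile(fileext = ".nii")
  write_volume(zero, f2)
  expect_true(all(read_volume(f2)$voxels == 0))
})

test_that("invalid volumes are rejected at construction and at read", {
  expect_error(image_volume(array(0, c(4, 4, 4)), c(-1, 1, 1)), "spacing")
  expect_error(image_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)),
               "non-finite")
  expect_error(read_volume(tempfile(fileext = ".nii")), "does not exist")
  expect_error(write_volume(image_volume(array(0, c(2, 2, 2)), c(1, 1, 1)),
                            file.path(tempfile(), "x", "y.nii")),
               "directory")
  # corrupt a written header to carry a negative spacing
  f <- tempfile(fileext = ".nii")
  write_volume(image_volume(array(1, c(4, 4, 4)), c(2, 1, 1)), f)
  con <- file(f, "r+b")
  seek(con, 80, rw = "write")
  writeBin(-2.0, con, size = 4)
  close(con)
  expect_error(read_volume(f), "invalid voxel spacing")
})

test_that("manifest loading validates rows and preserves patient grouping", {
  dir <- tempfile(); dir.create(dir)
  mk <- function(name) {
    write_volume(image_volume(array(rnorm(4 * 8 * 8), c(4, 8, 8)),
                              c(2, 1, 1)), file.path(dir, name))
    name
  }
  vols <- vapply(c("pre.nii", "p1.nii", "p2.nii", "t2.nii"), mk,
                 character(1))
  row <- data.frame(patient_id = "A", lesion_id = "A_L1", label = "benign",
                    seed_slice = 1, seed_row = 4, seed_col = 4,
                    dce_pre = "pre.nii", dce_post1 = "p1.nii",
                    dce_post2 = "p2.nii", t2w = "t2.nii")
  tab <- rbind(row,
               transform(row, lesion_id = "A_L2", label = "malignant"),
               transform(row, patient_id = "B", lesion_id = "B_L1"))
  man <- file.path(dir, "manifest.csv")
  write_manifest(tab, man)
  recs <- load_manifest(man)
  expect_length(recs, 3)
  expect_setequal(vapply(recs, `[[`, character(1), "patient_id"),
                  c("A", "B"))
  loaded <- load_study(recs[[1]])
  expect_s3_class(loaded$dce, "dynamic_series")
  expect_identical(dim(loaded$t2w$voxels), c(4L, 8L, 8L))

  # ambiguous label is rejected (the exclusion-rule analogue)
  bad <- transform(row, lesion_id = "A_L3", label = "suspicious")
  write_manifest(rbind(tab, bad), man)
  expect_error(load_manifest(man), "unknown label 'suspicious'")

  # out-of-grid seed aborts with a per-row report
  bad2 <- transform(row, lesion_id = "A_L4", seed_slice = 99)
  write_manifest(rbind(tab, bad2), man)
  expect_error(load_manifest(man), "A_L4.*outside DCE grid")

  # empty manifest: empty list with a warning
  write_manifest(tab[0, ], man)
  expect_warning(recs0 <- load_manifest(man), "empty")
  expect_length(recs0, 0)

  # missing column
  write_manifest(tab[, setdiff(names(tab), "t2w")], man)
  expect_error(load_manifest(man), "missing required columns: t2w")
})

test_that("mask transfer maps between grids by physical coordinates", {
  mask <- array(FALSE, c(8, 16, 16))
  mask[3:5, 6:9, 6:9] <- TRUE
  # identity geometry: exact copy
  out <- mask_to_frame(mask, c(2, 1, 1), c(0, 0, 0),
                       c(8, 16, 16), c(2, 1, 1), c(0, 0, 0))
  expect_identical(out, mask)
  # finer destination grid: volume approximately preserved
  out2 <- mask_to_frame(mask, c(2, 1, 1), c(0, 0, 0),
                        c(8L, 32L, 32L), c(2, 0.5, 0.5), c(0, 0, 0))
  v_src <- sum(mask) * 2
  v_dst <- sum(out2) * 2 * 0.25
  expect_lt(abs(v_dst - v_src) / v_src, 0.2)
  # a physical offset shifts the lookup
  out3 <- mask_to_frame(mask, c(2, 1, 1), c(0, 0, 0),
                        c(8, 16, 16), c(2, 1, 1), c(0, 0, 0),
                        offset_mm = c(0, 2, 0))
  expect_identical(out3[, 4:7, 6:9], mask[, 6:9, 6:9])
})
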