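test_that("subtraction volumes are voxelwise differences with inherited geometry", {
  set.seed(1)
  pre <- image_volume(array(rnorm(4 * 6 * 6), c(4, 6, 6)), c(2, 0.7, 0.7))
  v <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
  mk <- function(a) image_volume(a, c(2, 0.7, 0.7))
  s <- dynamic_series(pre, list(mk(pre$voxels), mk(pre$voxels + v)))
  expect_true(all(subtraction_volume(s, 1)$voxels == 0))
  expect_equal(subtraction_volume(s, 2)$voxels, v, tolerance = 1e-12)
  z <- dynamic_series(mk(array(0, c(4, 6, 6))), list(mk(v), mk(v)))
  expect_equal(subtraction_volume(z, 2)$voxels, v, tolerance = 1e-12)
  expect_error(subtraction_volume(s, 3), "outside")
})

test_that("MIP dominates every slice and matches the brute-force projection", {
  set.seed(2)
  a <- array(rnorm(5 * 8 * 8), c(5, 8, 8))
  m <- mip(image_volume(a, c(2, 1, 1)))
  brute <- apply(a, c(2, 3), max)
  expect_identical(m$pixels, brute)
  for (k in 1:5) expect_true(all(m$pixels >= a[k, , ]))
  # single-slice volume: identity
  one <- image_volume(a[1, , , drop = FALSE], c(2, 1, 1))
  expect_identical(mip(one)$pixels, a[1, , ])
})

test_that("centre-slice selection maximises lesion area with low-index ties", {
  msk <- array(FALSE, c(5, 6, 6))
  msk[2, 1:5, 1] <- TRUE              # area 5
  msk[3, 1:3, 1:3] <- TRUE            # area 9
  msk[4, 1:3, 1:3] <- TRUE            # area 9 (tie)
  msk[5, 1:2, 1] <- TRUE              # area 2
  t2 <- image_volume(array(rnorm(180), c(5, 6, 6)), c(2, 1, 1))
  cs <- select_center_slice(t2, msk)
  expect_identical(cs$slice, 2L)       # 0-based: first of the tied maxima
  expect_identical(cs$image$pixels, t2$voxels[3, , ])
  expect_error(select_center_slice(t2, array(FALSE, c(5, 6, 6))), "empty")
})

test_that("bicubic resampling reproduces constants, linears and the identity", {
  set.seed(3)
  img <- matrix(rnorm(40 * 30), 40, 30)
  r <- resample_inplane(img, c(1, 1), spacing = c(1, 1))
  expect_equal(r$pixels, img, tolerance = 1e-12)
  rc <- resample_inplane(matrix(3.7, 20, 20), 0.5, spacing = c(1, 1))
  expect_identical(dim(rc$pixels), c(40L, 40L))
  expect_equal(max(abs(rc$pixels - 3.7)), 0, tolerance = 1e-12)
  # linear ramp preserved away from borders
  ramp <- outer(0:39, rep(1, 30))
  rr <- resample_inplane(ramp, c(0.55, 0.55), spacing = c(1, 1))
  pos <- ((seq_len(nrow(rr$pixels)) - 0.5) * 0.55) - 0.5
  inner <- 5:(nrow(rr$pixels) - 5)
  expect_lt(max(abs(rr$pixels[inner, ] - outer(pos[inner],
                                               rep(1, ncol(rr$pixels))))),
            1e-6 * max(abs(ramp)))
  # physical extent preserved within one output pixel
  expect_lt(abs(nrow(rr$pixels) * 0.55 - 40 * 1), 0.55 + 1e-9)
})

test_that("ROI boxes are square, margin-padded and shift-clipped at borders", {
  fp <- matrix(FALSE, 30, 30); fp[10:19, 12:17] <- TRUE  # bbox 10 x 6
  b <- roi_box(fp)
  expect_identical(b[3] - b[1], 16L)
  expect_identical(b[4] - b[2], 16L)
  fp1 <- matrix(FALSE, 30, 30); fp1[5, 9] <- TRUE
  b1 <- roi_box(fp1)
  expect_identical(b1[3] - b1[1], 7L)
  expect_identical((b1[1] + b1[3] - 1L) %/% 2L, 4L)  # footprint centred
  # lesion at the image corner: box shifted inside, footprint contained
  fpc <- matrix(FALSE, 30, 30); fpc[1:4, 1:4] <- TRUE
  bc <- roi_box(fpc)
  expect_true(bc[1] >= 0 && bc[2] >= 0 && bc[3] <= 30 && bc[4] <= 30)
  expect_identical(bc[3] - bc[1], 10L)
  expect_true(all(which(fpc, arr.ind = TRUE)[, 1] - 1 >= bc[1]))
  expect_error(roi_box(matrix(TRUE, 30, 30)), "exceeds image")
  expect_error(roi_box(matrix(FALSE, 5, 5)), "empty")
})

test_that("paired crops share the box side and follow footprint shifts", {
  set.seed(4)
  i1 <- roi2d(matrix(rnorm(900), 30), c(1, 1), "dce_mip")
  i2 <- roi2d(matrix(rnorm(900), 30), c(1, 1), "t2w_center")
  fpa <- matrix(FALSE, 30, 30); fpa[10:15, 10:15] <- TRUE
  pr0 <- crop_pair(i1, i2, fpa, fpa)
  expect_identical(pr0$dce$box, pr0$t2w$box)
  fpb <- matrix(FALSE, 30, 30); fpb[15:20, 15:20] <- TRUE
  pr <- crop_pair(i1, i2, fpa, fpb)
  expect_identical(pr$t2w$box - pr$dce$box, c(5L, 5L, 5L, 5L))
  expect_identical(dim(pr$dce$pixels), dim(pr$t2w$pixels))
  # footprint centre lands at the box centre (within a pixel)
  ctr_fp <- c(mean(range(which(fpb, arr.ind = TRUE)[, 1])) - 1,
              mean(range(which(fpb, arr.ind = TRUE)[, 2])) - 1)
  ctr_box <- c((pr$t2w$box[1] + pr$t2w$box[3] - 1) / 2,
               (pr$t2w$box[2] + pr$t2w$box[4] - 1) / 2)
  expect_true(all(abs(ctr_fp - ctr_box) <= 1))
  expect_error(crop_pair(i1, roi2d(i2$pixels, c(0.5, 0.5)), fpa, fpb),
               "resolution-matched")
})

test_that("fusion composites put DCE in red, T2w in green and leave blue blank", {
  set.seed(5)
  i1 <- roi2d(matrix(rnorm(400), 20), c(1, 1), "dce_mip")
  i2 <- roi2d(matrix(rnorm(400), 20), c(1, 1), "t2w_center")
  fp <- matrix(FALSE, 20, 20); fp[8:12, 8:12] <- TRUE
  pr <- crop_pair(i1, i2, fp, fp)
  fu <- make_fusion(pr)
  expect_identical(sum(fu[, , 3]), 0)
  expect_identical(fu[, , 1], rescale01(pr$dce$pixels))
  expect_identical(fu[, , 2], rescale01(pr$t2w$pixels))
  # swapping the inputs swaps red and green exactly
  pr_sw <- pr; tmp <- pr_sw$dce; pr_sw$dce <- pr_sw$t2w; pr_sw$t2w <- tmp
  fu_sw <- make_fusion(pr_sw)
  expect_identical(fu_sw[, , 1], fu[, , 2])
  expect_identical(fu_sw[, , 2], fu[, , 1])
})
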