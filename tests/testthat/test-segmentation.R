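test_that("a noiseless two-level blob is recovered exactly", {
  a <- array(0, c(10, 20, 20))
  a[4:7, 8:13, 8:13] <- 100
  seg <- fcm_segment(image_volume(a, c(1, 1, 1)), c(5, 10, 10))
  # oracle: intensity threshold at the midpoint
  expect_identical(seg$mask, a > 50)
  expect_identical(seg$component_count, 1L)
})

test_that("FCM memberships are a partition of unity and the objective never increases", {
  set.seed(2)
  for (k in 2:4) {
    x <- c(rnorm(400), rnorm(80, 6), rnorm(40, 12))
    fit <- fcm_cluster(x, fcm_params(n_clusters = k))
    expect_lt(max(abs(rowSums(fit$membership) - 1)), 1e-9)
    expect_true(all(diff(fit$objective) <= 1e-8 * fit$objective[1]))
  }
})

test_that("segmentation is invariant to affine intensity rescaling", {
  set.seed(3)
  a <- array(rnorm(8 * 24 * 24, 0, 0.05), c(8, 24, 24))
  a[3:6, 9:16, 9:16] <- a[3:6, 9:16, 9:16] + 1
  v1 <- image_volume(a, c(1, 1, 1))
  v2 <- image_volume(7 * a - 3, c(1, 1, 1))
  s1 <- fcm_segment(v1, c(4, 12, 12))
  s2 <- fcm_segment(v2, c(4, 12, 12))
  expect_identical(s1$mask, s2$mask)
})

test_that("phantom lesions are segmented with high Dice overlap", {
  set.seed(4)
  p <- phantom_params(noise_sd = 0.02)
  for (cls in c("benign", "malignant")) {
    st <- generate_study(p, "P", "L", cls, diameter_mm = 12)
    sub <- subtraction_volume(st$record$dce, 2)
    seg <- fcm_segment(sub, st$record$seed_point)
    expect_gte(dice_overlap(seg$mask, st$truth$mask_dce), 0.8)
  }
})

test_that("a seed in flat background fails rather than segmenting noise", {
  set.seed(9)
  a <- array(rnorm(8 * 20 * 20), c(8, 20, 20))
  a[3:5, 4:7, 4:7] <- a[3:5, 4:7, 4:7] + 20   # lesion far from the seed
  expect_error(fcm_segment(image_volume(a, c(1, 1, 1)), c(4, 15, 15)),
               "seed outside segmentation|search box")
  expect_error(fcm_segment(image_volume(a, c(1, 1, 1)), c(4, 50, 2)),
               "outside the voxel grid")
})

test_that("effective diameter follows the equal-volume-sphere formula", {
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(effective_diameter(single, c(1, 1, 1)), (6 / pi)^(1 / 3),
               tolerance = 1e-12)
  # digital ball of radius 10, isotropic 1 mm: diameter 20 within 5%
  g <- expand.grid(i = -12:12, j = -12:12, k = -12:12)
  ball <- array((g$i^2 + g$j^2 + g$k^2) <= 100, c(25, 25, 25))
  expect_equal(effective_diameter(ball, c(1, 1, 1)), 20, tolerance = 1)
  # doubling the spacing doubles the diameter
  expect_equal(effective_diameter(ball, c(2, 2, 2)),
               2 * effective_diameter(ball, c(1, 1, 1)), tolerance = 1e-12)
  expect_error(effective_diameter(array(FALSE, c(2, 2, 2)), c(1, 1, 1)),
               "empty mask")
})

test_that("FCM agrees with an independent fuzzy clustering implementation", {
  set.seed(11)
  x <- c(rnorm(300, 0, 0.5), rnorm(100, 5, 0.5))
  ours <- fcm_cluster(x, fcm_params())
  ref <- e1071::cmeans(matrix(x), centers = matrix(sort(ours$centers)),
                       m = 2, method = "cmeans")
  expect_equal(sort(ours$centers), sort(as.numeric(ref$centers)),
               tolerance = 1e-3)
  hard_ours <- apply(ours$membership, 1, which.max)
  hard_ref <- as.integer(ref$cluster)
  agree <- mean((hard_ours == which.max(ours$centers)) ==
                  (hard_ref == which.max(ref$centers)))
  expect_gte(agree, 0.99)
})
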