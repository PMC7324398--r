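test_that("auc_mw equals pairwise enumeration, including ties", {
  # worked example: pairs (0.35 vs 0.1, 0.35 vs 0.4, 0.8 vs 0.1, 0.8 vs 0.4)
  expect_equal(auc_mw(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75,
               tolerance = 1e-12)
  expect_equal(auc_mw(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1, tolerance = 1e-12)
  expect_equal(auc_mw(rep(3, 10), rep(c(0, 1), 5)), 0.5, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:60) {
    n <- sample(6:50, 1)
    s <- round(rnorm(n), 1)             # coarse scores force ties
    l <- rbinom(n, 1, 0.5)
    if (sum(l) == 0 || sum(l) == n) next
    pos <- s[l == 1]; neg <- s[l == 0]
    brute <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(auc_mw(s, l), brute, tolerance = 1e-12)
  }
  expect_error(auc_mw(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("the DeLong test matches its structural identities and a jackknife oracle", {
  s <- c(0.1, 0.4, 0.35, 0.8); l <- c(0, 0, 1, 1)
  d0 <- delong_test(s, s, l)
  expect_identical(d0$p_value, 1)
  expect_identical(d0$delta_auc, 0)
  set.seed(2)
  for (i in 1:20) {
    n <- 30
    s1 <- rnorm(n); s2 <- 0.5 * s1 + rnorm(n); l <- rbinom(n, 1, 0.5)
    if (sum(l) < 3 || sum(l) > n - 3) next
    d <- delong_test(s1, s2, l)
    # component means ARE the Mann-Whitney AUCs
    expect_equal(d$auc_a, auc_mw(s1, l), tolerance = 1e-12)
    expect_equal(d$auc_b, auc_mw(s2, l), tolerance = 1e-12)
    expect_true(d$ci95[1] <= d$delta_auc && d$delta_auc <= d$ci95[2])
    # leave-one-out jackknife oracle for the variance of the AUC difference
    jack <- vapply(seq_len(n), function(j)
      auc_mw(s1[-j], l[-j]) - auc_mw(s2[-j], l[-j]), numeric(1))
    vjack <- (n - 1) / n * sum((jack - mean(jack))^2)
    expect_equal(d$se^2, vjack, tolerance = 0.1)
  }
})

test_that("the DeLong test agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  s1 <- rnorm(40); s2 <- 0.6 * s1 + rnorm(40); l <- rbinom(40, 1, 0.6)
  d <- delong_test(s1, s2, l)
  ref <- pROC::roc.test(pROC::roc(l, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(l, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(d$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("bootstrap CIs are seeded, degenerate at perfect separation, and shrink with n", {
  b <- bootstrap_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), B = 300,
                    seed = 4)
  expect_identical(b$ci95, c(1, 1))
  b2 <- bootstrap_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), B = 300,
                     seed = 4)
  expect_identical(b, b2)
  set.seed(5)
  mk <- function(n) {
    l <- rbinom(n, 1, 0.5)
    list(s = rnorm(n) + l, l = l)
  }
  small <- mk(50); big <- mk(500)
  ci_small <- bootstrap_ci(small$s, small$l, B = 400, seed = 6)
  ci_big <- bootstrap_ci(big$s, big$l, B = 400, seed = 6)
  expect_lt(diff(ci_big$ci95), diff(ci_small$ci95))
  expect_warning(bootstrap_ci(small$s, small$l, B = 50, seed = 1),
                 "very small")
})

test_that("Holm correction matches the step-down recipe and is monotone", {
  expect_equal(holm_correct(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06),
               tolerance = 1e-12)
  expect_identical(holm_correct(0.2), 0.2)
  expect_identical(holm_correct(rep(1, 4)), rep(1, 4))
  expect_identical(holm_correct(numeric(0)), numeric(0))
  set.seed(7)
  p <- runif(10)
  adj <- holm_correct(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("the operating point minimises m with sensitivity tie-breaks", {
  op <- operating_point(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_identical(op$m_value, 0)
  expect_identical(op$sensitivity, 1)
  expect_identical(op$ppv, 1)
  # the m metric itself at a published-style operating point
  expect_equal((1 - 0.759)^2 + (1 - 0.765)^2, 0.1133, tolerance = 1e-3)
  set.seed(8)
  s <- runif(80); l <- rbinom(80, 1, 0.6)
  op2 <- operating_point(s, l)
  call_pos <- s >= op2$threshold
  tp <- sum(call_pos & l == 1); fp <- sum(call_pos & l == 0)
  fn <- sum(!call_pos & l == 1); tn <- sum(!call_pos & l == 0)
  expect_equal(op2$ppv, tp / (tp + fp), tolerance = 1e-12)
  expect_equal(op2$npv, tn / (tn + fn), tolerance = 1e-12)
  expect_equal(op2$m_value,
               (1 - op2$sensitivity)^2 + (1 - op2$specificity)^2,
               tolerance = 1e-12)
})

test_that("equivalence requires the CI strictly inside the margin", {
  expect_true(equivalence_test(c(-0.01, 0.02)))
  expect_false(equivalence_test(c(-0.06, 0.01)))
  expect_false(equivalence_test(c(-0.05, 0.05)))  # open-interval rule
  expect_error(equivalence_test(c(-0.01, 0.01), margin = 0), "positive")
})

test_that("compare_all produces the 3x2 grid with per-scheme metrics", {
  set.seed(9)
  n <- 60
  lab <- rbinom(n, 1, 0.6)
  base <- data.frame(lesion_id = sprintf("L%02d", 1:n),
                     patient_id = sprintf("P%02d", 1:n),
                     label = ifelse(lab == 1, "malignant", "benign"),
                     outer_fold = 1L)
  mk <- function(scheme, s) cbind(base, scheme = scheme, pm = s)
  s_dce <- plogis(rnorm(n) + lab)
  pm <- rbind(mk("dce", s_dce), mk("t2w", plogis(rnorm(n) + 0.5 * lab)),
              mk("image_fusion", s_dce),     # identical to dce on purpose
              mk("feature_fusion", plogis(rnorm(n) + 1.5 * lab)),
              mk("classifier_fusion", plogis(rnorm(n) + lab)))
  class(pm) <- c("pm_table", "data.frame")
  rep <- compare_all(pm, B = 200, seed = 1)
  expect_identical(nrow(rep$comparisons), 6L)
  expect_identical(nrow(rep$schemes), 5L)
  cell <- rep$comparisons[rep$comparisons$fusion == "image_fusion" &
                            rep$comparisons$single == "dce", ]
  expect_identical(cell$delta_auc, 0)
  expect_identical(cell$corrected_p, 1)
  expect_true(all(rep$comparisons$corrected_p >= rep$comparisons$p_value))
  expect_error(compare_all(pm[pm$scheme != "t2w", ]), "missing scheme")
})
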