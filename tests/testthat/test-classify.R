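test_that("cross-validation plans group patients, stratify and reproduce", {
  sf <- synthetic_features(n_patients = 40, prevalence = 0.6, seed = 2)
  plan <- make_cv_plan(sf$meta, k = 5, seed = 9)
  # every lesion of a patient shares its fold
  per_pat <- tapply(plan$fold, sf$meta$patient_id,
                    function(f) length(unique(f)))
  expect_true(all(per_pat == 1))
  # every patient in exactly one fold; folds near-balanced in patients
  expect_setequal(names(plan$fold_of_patient), unique(sf$meta$patient_id))
  expect_lte(diff(range(table(plan$fold_of_patient))), 2)
  # per-fold prevalence within 5 points of the cohort prevalence
  prev <- mean(sf$meta$label == "malignant")
  fold_prev <- tapply(sf$meta$label == "malignant", plan$fold, mean)
  expect_true(all(abs(fold_prev - prev) <= 0.05 + 1e-9))
  # determinism
  plan2 <- make_cv_plan(sf$meta, k = 5, seed = 9)
  expect_identical(plan$fold_of_patient, plan2$fold_of_patient)
  # impossible stratification errors
  tiny <- sf$meta[sf$meta$patient_id %in% unique(sf$meta$patient_id)[1:4], ]
  expect_error(make_cv_plan(tiny, k = 5), "impossible stratification")
})

test_that("nested CV split fractions are 64/16/20 up to rounding", {
  sf <- synthetic_features(n_patients = 40, seed = 3)
  plan <- make_cv_plan(sf$meta, k = 5, seed = 1)
  n <- nrow(sf$meta)
  for (f in 1:5) {
    n_test <- sum(plan$fold == f)
    train_meta <- sf$meta[plan$fold != f, ]
    inner <- make_cv_plan(train_meta, k = 5, seed = 11, tol = Inf)
    for (g in 1:5) {
      n_val <- sum(inner$fold == g)
      n_train <- nrow(train_meta) - n_val
      expect_lt(abs(n_test / n - 0.20), 0.05)
      expect_lt(abs(n_val / n - 0.16), 0.05)
      expect_lt(abs(n_train / n - 0.64), 0.10)
    }
  }
})

test_that("prior rescaling follows the odds formula and preserves ranks", {
  expect_equal(rescale_pm(0.785, 0.785), 0.5, tolerance = 1e-12)
  expect_equal(rescale_pm(0.9, 0.5), 0.9, tolerance = 1e-12)
  p <- 0.785 * 2 / (1 + 0.785)
  odds <- (p / 0.785) / ((1 - p) / (1 - 0.785))
  expect_equal(rescale_pm(p, 0.785), odds / (1 + odds), tolerance = 1e-12)
  expect_identical(rescale_pm(c(0, 1), 0.3), c(0, 1))
  expect_error(rescale_pm(0.5, 1), "prevalence")
  # strictly increasing => AUC invariant
  set.seed(4)
  s <- runif(60); l <- rbinom(60, 1, 0.5)
  expect_true(all(diff(rescale_pm(sort(s), 0.785)) > 0))
  expect_equal(auc_mw(rescale_pm(s, 0.785), l), auc_mw(s, l),
               tolerance = 1e-12)
})

test_that("nested training recovers signal, respects grouping and fails on noise", {
  sf <- synthetic_features(n_patients = 40, shift = 2, prevalence = 0.5,
                           seed = 5)
  plan <- make_cv_plan(sf$meta, k = 5, seed = 21)
  pm <- train_eval_scheme(sf$features, sf$meta, plan, small_grid(), "dce")
  expect_identical(nrow(pm), nrow(sf$meta))
  expect_true(all(pm$pm >= 0 & pm$pm <= 1))
  expect_gt(auc_mw(pm$pm, pm$label == "malignant"), 0.9)
  # test-fold lesions never share a patient with training folds
  for (f in 1:5) {
    te_pat <- unique(pm$patient_id[pm$outer_fold == f])
    tr_pat <- unique(sf$meta$patient_id[plan$fold != f])
    expect_length(intersect(te_pat, tr_pat), 0)
  }
  # permuted labels: chance-level AUC
  set.seed(99)
  meta_perm <- sf$meta
  meta_perm$label <- sample(meta_perm$label)
  plan_p <- make_cv_plan(meta_perm, k = 5, seed = 21, tol = Inf)
  pm_p <- train_eval_scheme(sf$features, meta_perm, plan_p, small_grid(),
                            "dce")
  auc_p <- auc_mw(pm_p$pm, pm_p$label == "malignant")
  expect_gt(auc_p, 0.35)
  expect_lt(auc_p, 0.65)
  # key mismatch errors
  bad <- sf$features[-1, ]
  expect_error(train_eval_scheme(bad, sf$meta, plan, small_grid()),
               "key mismatch")
})

test_that("classifier fusion averages PMs and matches a rank-based oracle", {
  sf <- synthetic_features(n_patients = 20, seed = 6)
  mk_pm <- function(seed) {
    set.seed(seed)
    structure(data.frame(lesion_id = sf$meta$lesion_id,
                         patient_id = sf$meta$patient_id,
                         label = sf$meta$label, outer_fold = 1L,
                         scheme = "x", pm = runif(nrow(sf$meta))),
              class = c("pm_table", "data.frame"))
  }
  a <- mk_pm(1); b <- mk_pm(2)
  fu <- classifier_fusion(a, b)
  expect_equal(fu$pm, (a$pm + b$pm) / 2, tolerance = 1e-12)
  expect_identical(unique(fu$scheme), "classifier_fusion")
  same <- classifier_fusion(a, a)
  expect_equal(same$pm, a$pm, tolerance = 1e-12)
  # AUC of the average equals a brute-force Mann-Whitney on averaged scores
  lab <- fu$label == "malignant"
  avg <- (a$pm + b$pm) / 2
  pos <- avg[lab]; neg <- avg[!lab]
  brute <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(auc_mw(fu$pm, lab), brute, tolerance = 1e-12)
  b_bad <- b[-1, ]
  expect_error(classifier_fusion(a, b_bad), "identical lesion sets")
})

test_that("repeated seeded runs are stable and identical seeds give zero spread", {
  sf <- synthetic_features(n_patients = 36, shift = 2, seed = 7)
  rep0 <- reproducibility_runs(sf$features, sf$meta, grid = small_grid(),
                               seeds = c(5, 5))
  expect_identical(rep0$se_auc, 0)
  rep1 <- reproducibility_runs(sf$features, sf$meta, n_runs = 3,
                               base_seed = 31, grid = small_grid())
  expect_true(rep1$mean_auc >= min(rep1$aucs) &&
                rep1$mean_auc <= max(rep1$aucs))
  expect_lt(rep1$se_auc, 0.1)
})
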