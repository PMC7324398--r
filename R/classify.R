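# Class-weighted RBF-SVM classification under nested patient-grouped
# cross-validation, producing calibrated posterior probabilities of
# malignancy (PMs) for every scheme.
#
# Outer 5-fold CV partitions PATIENTS (all lesions of a patient share a
# fold, stratified so per-fold class prevalence stays near the cohort's).
# Per outer fold: standardise to the training fold, PCA (95% retained
# variance) fit on training only, (gamma, C) selected by an inner 5-fold
# patient-grouped grid search maximising inner AUC, final fit with
# inverse-prevalence class weights, sigmoid calibration on training decision
# values, and rescaling of the calibrated probabilities to a 50% prior.
# Test-fold PMs from the five outer folds are aggregated.

#' Hyperparameter grid for the RBF-SVM
#'
#' @param gamma_values kernel scale grid (log-spaced).
#' @param C_values regularisation grid (log-spaced).
#' @return A `hyper_grid` list.
#' @export
hyper_grid <- function(gamma_values = 10^seq(-5, 1, length.out = 7),
                       C_values = 10^seq(-2, 4, length.out = 7)) {
  stopifnot(all(gamma_values > 0), all(C_values > 0))
  structure(list(gamma_values = gamma_values, C_values = C_values),
            class = "hyper_grid")
}

#' Patient-grouped stratified cross-validation plan
#'
#' Partitions patients into `k` folds such that every lesion of a patient
#' lands in the same fold and per-fold lesion-level class prevalence stays
#' within 5 percentage points of the cohort prevalence (patients are
#' stratified by their majority label; repeated seeded shuffles pick the
#' best-balanced assignment).
#'
#' @param meta data.frame with columns `patient_id`, `lesion_id`, `label`.
#' @param k number of folds (default 5).
#' @param seed RNG seed; equal seeds give identical plans.
#' @param max_tries shuffle attempts before giving up on the prevalence
#'   constraint.
#' @param tol allowed per-fold prevalence deviation (default 5 percentage
#'   points). `Inf` gives the best-balanced plan found without erroring,
#'   which is appropriate for inner folds on small training subsets.
#' @return A `cv_plan`: list with `fold_of_patient` (named integer vector),
#'   `fold` (per-lesion fold, aligned with `meta`), `k`, `seed`.
#' @export
make_cv_plan <- function(meta, k = 5L, seed = 1L, max_tries = 200L,
                         tol = 0.05) {
  stopifnot(all(c("patient_id", "lesion_id", "label") %in% names(meta)),
            all(meta$label %in% c("benign", "malignant")))
  pat <- split(meta$label, meta$patient_id)
  maj <- vapply(pat, function(l)
    names(sort(table(factor(l, c("benign", "malignant"))),
               decreasing = TRUE))[1], character(1))
  n_per_class <- table(factor(maj, c("benign", "malignant")))
  if (is.finite(tol) && any(n_per_class < k))
    stop("impossible stratification: need at least ", k,
         " patients per majority class, have ",
         paste(n_per_class, collapse = "/"))
  prev <- mean(meta$label == "malignant")
  rs <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(seed)

  best <- NULL; best_dev <- Inf
  for (try in seq_len(max_tries)) {
    fold_of_patient <- integer(length(pat))
    names(fold_of_patient) <- names(pat)
    assigned <- 0L
    for (cls in c("benign", "malignant")) {
      ids <- sample(names(pat)[maj == cls])
      # continue the round-robin across strata so total per-fold patient
      # counts stay balanced and no fold is left empty unnecessarily
      fold_of_patient[ids] <- (assigned + seq_along(ids) - 1L) %% k + 1L
      assigned <- assigned + length(ids)
    }
    fold <- fold_of_patient[meta$patient_id]
    fold_prev <- vapply(seq_len(k), function(f)
      mean(meta$label[fold == f] == "malignant"), numeric(1))
    dev <- if (anyNA(fold_prev)) Inf else max(abs(fold_prev - prev))
    if (is.null(best) || dev < best_dev) {
      best <- fold_of_patient; best_dev <- dev
    }
    if (best_dev <= tol) break
  }
  if (best_dev > tol)
    stop("impossible stratification: fold prevalence deviates by ",
         round(best_dev * 100, 1), " points after ", max_tries, " tries")
  structure(list(fold_of_patient = best,
                 fold = unname(best[meta$patient_id]),
                 k = as.integer(k), seed = as.integer(seed),
                 prevalence_deviation = best_dev),
            class = "cv_plan")
}

#' Rescale a calibrated probability to a 50% prior
#'
#' Converts a posterior computed under the training prevalence pi to the
#' posterior under a scaled prevalence of 50%:
#' pm = (p/pi) / (p/pi + (1-p)/(1-pi)). Strictly increasing in p, so score
#' ranks — and hence AUC — are unchanged.
#'
#' @param p calibrated probability in \[0, 1\] (0 and 1 map to themselves).
#' @param prevalence training-set malignant prevalence, in (0, 1).
#' @return probability of malignancy at a 50% prior.
#' @export
rescale_pm <- function(p, prevalence) {
  if (any(prevalence <= 0) || any(prevalence >= 1))
    stop("prevalence must lie strictly inside (0, 1)")
  stopifnot(all(p >= 0), all(p <= 1))
  odds <- (p / prevalence) / ((1 - p) / (1 - prevalence))
  out <- odds / (1 + odds)
  out[p == 0] <- 0
  out[p == 1] <- 1
  out
}

# Decision values oriented so that larger means more malignant.
.svm_decision <- function(fit, x) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")
  cn <- colnames(dv)[1]
  if (identical(cn, "benign/malignant")) -dv[, 1] else dv[, 1]
}

.fit_svm <- function(x, y, gamma, cost) {
  wt <- length(y) / (2 * table(y))
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             gamma = gamma, cost = cost,
             class.weights = c(benign = unname(wt["benign"]),
                               malignant = unname(wt["malignant"])),
             scale = FALSE)
}

#' Train and evaluate one classification scheme
#'
#' Runs the full nested patient-grouped cross-validation for one scheme and
#' returns the aggregated test-fold PM table. For `scheme =
#' "feature_fusion"` pass the column-wise concatenation of the DCE and T2w
#' feature tables.
#'
#' @param features numeric matrix, rows keyed by lesion id (rownames).
#' @param meta data.frame with `patient_id`, `lesion_id`, `label` aligned to
#'   the cohort.
#' @param plan a `cv_plan` from [make_cv_plan()].
#' @param grid a `hyper_grid`.
#' @param scheme scheme tag recorded in the PM table.
#' @param pca_var retained-variance fraction for the training-fold PCA.
#' @param inner_k inner CV folds for the grid search.
#' @return A `pm_table` data.frame: `lesion_id`, `patient_id`, `label`,
#'   `outer_fold`, `scheme`, `pm`.
#' @export
train_eval_scheme <- function(features, meta, plan, grid = hyper_grid(),
                              scheme = "dce", pca_var = 0.95, inner_k = 5L) {
  stopifnot(inherits(plan, "cv_plan"))
  if (!all(meta$lesion_id %in% rownames(features)))
    stop("feature/label key mismatch: missing lesions ",
         paste(setdiff(meta$lesion_id, rownames(features)), collapse = ", "))
  x_all <- features[meta$lesion_id, , drop = FALSE]
  y_all <- factor(meta$label, c("benign", "malignant"))

  out <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    tr <- plan$fold != f
    te <- !tr
    if (length(unique(y_all[tr])) < 2L)
      stop("training folds for outer fold ", f, " contain a single class")
    # standardise to training-fold statistics
    mu <- colMeans(x_all[tr, , drop = FALSE])
    sd <- apply(x_all[tr, , drop = FALSE], 2, stats::sd)
    sd[sd == 0] <- 1
    xs_tr <- sweep(sweep(x_all[tr, , drop = FALSE], 2, mu), 2, sd, "/")
    xs_te <- sweep(sweep(x_all[te, , drop = FALSE], 2, mu), 2, sd, "/")
    # variance-preserving linear projection fit on training only
    pc <- stats::prcomp(xs_tr, center = FALSE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- max(which(cum >= pca_var)[1], 2L)
    xp_tr <- pc$x[, seq_len(ncomp), drop = FALSE]
    xp_te <- xs_te %*% pc$rotation[, seq_len(ncomp), drop = FALSE]

    # inner patient-grouped grid search maximising mean inner-fold AUC
    meta_tr <- meta[tr, , drop = FALSE]
    inner <- make_cv_plan(meta_tr, k = inner_k,
                          seed = plan$seed * 1000L + f, tol = Inf)
    combos <- expand.grid(C = grid$C_values, gamma = grid$gamma_values)
    inner_auc <- vapply(seq_len(nrow(combos)), function(ci) {
      aucs <- vapply(seq_len(inner_k), function(g) {
        itr <- inner$fold != g; ite <- !itr
        yv <- y_all[tr][ite]
        if (length(unique(y_all[tr][itr])) < 2L ||
            length(unique(yv)) < 2L) return(NA_real_)
        fit <- .fit_svm(xp_tr[itr, , drop = FALSE], y_all[tr][itr],
                        combos$gamma[ci], combos$C[ci])
        auc_mw(.svm_decision(fit, xp_tr[ite, , drop = FALSE]),
               yv == "malignant")
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    bi <- which.max(inner_auc)

    fit <- .fit_svm(xp_tr, y_all[tr], combos$gamma[bi], combos$C[bi])
    dv_tr <- .svm_decision(fit, xp_tr)
    # sigmoid (Platt-style) calibration on training decision values
    cal <- suppressWarnings(stats::glm((y_all[tr] == "malignant") ~ dv_tr,
                                       family = stats::binomial()))
    dv_te <- .svm_decision(fit, xp_te)
    p <- suppressWarnings(
      stats::predict(cal, data.frame(dv_tr = dv_te), type = "response"))
    p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
    pm <- rescale_pm(p, mean(y_all[tr] == "malignant"))
    out[[f]] <- data.frame(lesion_id = meta$lesion_id[te],
                           patient_id = meta$patient_id[te],
                           label = meta$label[te],
                           outer_fold = f, scheme = scheme, pm = pm,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pm_table", "data.frame")
  res
}

#' Classifier-level fusion by soft voting
#'
#' Averages the per-lesion PM outputs of the DCE and T2w classifiers.
#'
#' @param pm_dce,pm_t2w `pm_table`s over the same lesion set.
#' @return A `pm_table` with scheme `"classifier_fusion"`.
#' @export
classifier_fusion <- function(pm_dce, pm_t2w) {
  if (!setequal(pm_dce$lesion_id, pm_t2w$lesion_id))
    stop("classifier fusion requires identical lesion sets")
  m <- match(pm_dce$lesion_id, pm_t2w$lesion_id)
  out <- pm_dce
  out$pm <- (pm_dce$pm + pm_t2w$pm[m]) / 2
  out$scheme <- "classifier_fusion"
  class(out) <- c("pm_table", "data.frame")
  out
}

#' Repeated cross-validation runs with different seeds
#'
#' Reruns the CV split and the full nested training `n_runs` times with
#' consecutive seeds and summarises the spread of the aggregated AUCs — the
#' stability check for the choice of random seed.
#'
#' @param features,meta,grid,scheme,pca_var as in [train_eval_scheme()].
#' @param n_runs number of repetitions (>= 2).
#' @param base_seed first CV seed; run r uses `base_seed + r - 1`.
#' @param k outer folds.
#' @param seeds optional explicit seed vector overriding `base_seed`/`n_runs`.
#' @param tol fold-prevalence tolerance passed to [make_cv_plan()]; a run
#'   whose seed cannot satisfy it falls back to the best-balanced plan.
#' @return list(`mean_auc`, `se_auc` (SD across runs), `aucs`).
#' @export
reproducibility_runs <- function(features, meta, n_runs = 100L,
                                 base_seed = 1L, grid = hyper_grid(),
                                 scheme = "dce", pca_var = 0.95, k = 5L,
                                 seeds = NULL, tol = 0.05) {
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_runs) - 1L
  if (length(seeds) < 2) stop("need at least 2 runs")
  aucs <- vapply(seeds, function(s) {
    plan <- tryCatch(make_cv_plan(meta, k = k, seed = s, tol = tol),
                     error = function(e)
                       make_cv_plan(meta, k = k, seed = s, tol = Inf))
    pm <- train_eval_scheme(features, meta, plan, grid, scheme, pca_var)
    auc_mw(pm$pm, pm$label == "malignant")
  }, numeric(1))
  list(mean_auc = mean(aucs), se_auc = stats::sd(aucs), aucs = aucs)
}
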