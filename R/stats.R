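# Figures of merit and statistical inference: empirical ROC/AUC, bootstrap
# CIs, paired DeLong AUC comparisons with Bonferroni-Holm correction,
# operating-point clinical metrics, and AUC equivalence testing.

#' Mann-Whitney AUC
#'
#' Empirical AUC as the Mann-Whitney statistic: the mean over all
#' (positive, negative) pairs of \[score_pos > score_neg\] + 1/2 \[tie\].
#' Computed via midranks, which is exactly the pairwise enumeration.
#'
#' @param scores numeric score vector (larger = more malignant).
#' @param labels logical or 0/1 vector; `TRUE`/1 = positive (malignant).
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 (per positive) and V01 (per negative).
.delong_components <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)),
                numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)),
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong comparison of two AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors over the same
#' cases, using the structural-component covariance estimator: the AUC of
#' each classifier is the mean of its positive-case components, the
#' variance of the AUC difference follows from the empirical covariance of
#' the paired components, z = dAUC / SE with a two-sided normal p-value, and
#' a 95% CI dAUC +- 1.96 SE.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels positive-class indicator, common to both.
#' @return A `paired_comparison`: list with `auc_a`, `auc_b`, `delta_auc`,
#'   `se`, `z`, `p_value`, `ci95`, and `corrected_p` (NA until a
#'   multiplicity correction fills it in).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ca <- .delong_components(scores_a, labels)
  cb <- .delong_components(scores_b, labels)
  s10 <- stats::var(ca$v10 - cb$v10)
  s01 <- stats::var(ca$v01 - cb$v01)
  se <- sqrt(s10 / n1 + s01 / n0)
  delta <- ca$auc - cb$auc
  if (se == 0) {
    if (abs(delta) < .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      stop("non-informative scores: zero variance of the AUC difference")
    }
  } else {
    z <- delta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, delta_auc = delta, se = se,
                 z = z, p_value = p,
                 ci95 = delta + c(-1, 1) * stats::qnorm(0.975) * se,
                 corrected_p = NA_real_),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison> dAUC = %.4f (%.4f vs %.4f), 95%% CI [%.4f, %.4f], p = %.4g\n",
    x$delta_auc, x$auc_a, x$auc_b, x$ci95[1], x$ci95[2], x$p_value))
  invisible(x)
}

#' Bootstrap AUC confidence interval
#'
#' Case-resampling bootstrap over lesions: B resamples of the (score, label)
#' pairs, percentile 95% CI, SE as the resample standard deviation.
#' Resamples that lose a class are redrawn.
#'
#' @param scores,labels as in [auc_mw()].
#' @param B number of bootstrap samples (default 2000; < 100 warns).
#' @param seed RNG seed; equal seeds give identical CIs.
#' @return list(`auc`, `se`, `ci95`).
#' @export
bootstrap_ci <- function(scores, labels, B = 2000L, seed = 1L) {
  labels <- as.logical(labels)
  if (sum(labels) == 0L || sum(!labels) == 0L)
    stop("both classes must be present")
  if (B < 100L) warning("B = ", B, " bootstrap samples is very small")
  rs <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(seed)
  n <- length(scores)
  aucs <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(labels[idx]) && any(!labels[idx])) break
    }
    aucs[b] <- auc_mw(scores[idx], labels[idx])
  }
  list(auc = auc_mw(scores, labels), se = stats::sd(aucs),
       ci95 = unname(stats::quantile(aucs, c(0.025, 0.975))))
}

#' Bonferroni-Holm correction
#'
#' Step-down adjusted p-values (monotonicity enforced, capped at 1),
#' controlling the family-wise error rate.
#'
#' @param p_values numeric vector of raw p-values in (0, 1\].
#' @return adjusted p-values in the input order.
#' @export
holm_correct <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stopifnot(all(p_values > 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "holm")
}

#' Optimal ROC operating point
#'
#' Sweeps all empirical thresholds (call malignant when score >= t) and
#' returns the point minimising m = (1 - sensitivity)^2 +
#' (1 - specificity)^2; ties go to the higher sensitivity. PPV and NPV are
#' computed from the confusion counts at the selected threshold (test-set
#' prevalence).
#'
#' @param scores,labels as in [auc_mw()].
#' @return An `operating_point`: list(`threshold`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `m_value`).
#' @export
operating_point <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  thr <- sort(unique(scores))
  best <- NULL
  for (t in thr) {
    call_pos <- scores >= t
    tp <- sum(call_pos & labels); fp <- sum(call_pos & !labels)
    sens <- tp / n1; spec <- (n0 - fp) / n0
    m <- (1 - sens)^2 + (1 - spec)^2
    if (is.null(best) || m < best$m_value - 1e-12 ||
        (abs(m - best$m_value) <= 1e-12 && sens > best$sensitivity)) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   npv = if (n1 + n0 - tp - fp > 0)
                     (n0 - fp) / (n1 + n0 - tp - fp) else NA_real_,
                   m_value = m)
    }
  }
  structure(best, class = "operating_point")
}

#' AUC equivalence test by confidence-interval inclusion
#'
#' Two classifiers are declared equivalent when the 95% CI of their AUC
#' difference lies entirely inside the open interval (-margin, +margin) —
#' operationally the two-one-sided-tests rule at 5%.
#'
#' @param delta_auc_ci95 length-2 CI of the AUC difference.
#' @param margin equivalence margin (default 0.05, chosen prima facie).
#' @return `TRUE` if equivalent.
#' @export
equivalence_test <- function(delta_auc_ci95, margin = 0.05) {
  if (margin <= 0) stop("equivalence margin must be positive")
  stopifnot(length(delta_auc_ci95) == 2L, all(is.finite(delta_auc_ci95)))
  all(delta_auc_ci95 > -margin) && all(delta_auc_ci95 < margin)
}

#' Full five-scheme comparison report
#'
#' Per-scheme AUC with bootstrap CI and operating-point metrics, plus the
#' 3 x 2 grid of paired DeLong comparisons (each fusion scheme vs each
#' single-sequence scheme) with Bonferroni-Holm correction across the six
#' tests.
#'
#' @param pm a `pm_table` containing all five schemes (`dce`, `t2w`,
#'   `image_fusion`, `feature_fusion`, `classifier_fusion`) over one lesion
#'   set.
#' @param B bootstrap samples per scheme.
#' @param seed bootstrap seed.
#' @return A `cadx_report`: list(`schemes` data.frame, `comparisons`
#'   data.frame with 6 rows).
#' @export
compare_all <- function(pm, B = 2000L, seed = 1L) {
  singles <- c("dce", "t2w")
  fusions <- c("image_fusion", "feature_fusion", "classifier_fusion")
  missing <- setdiff(c(singles, fusions), unique(pm$scheme))
  if (length(missing))
    stop("PM table is missing scheme(s): ", paste(missing, collapse = ", "))
  wide <- lapply(c(singles, fusions), function(s) {
    sub <- pm[pm$scheme == s, ]
    sub[order(sub$lesion_id), ]
  })
  names(wide) <- c(singles, fusions)
  ids <- wide[[1]]$lesion_id
  labels <- wide[[1]]$label == "malignant"
  for (s in names(wide))
    if (!identical(wide[[s]]$lesion_id, ids))
      stop("schemes cover different lesion sets")

  schemes <- do.call(rbind, lapply(names(wide), function(s) {
    sc <- wide[[s]]$pm
    bs <- bootstrap_ci(sc, labels, B = B, seed = seed)
    op <- operating_point(sc, labels)
    data.frame(scheme = s, auc = bs$auc, auc_se = bs$se,
               ci_lo = bs$ci95[1], ci_hi = bs$ci95[2],
               sensitivity = op$sensitivity, specificity = op$specificity,
               ppv = op$ppv, npv = op$npv, m_value = op$m_value,
               stringsAsFactors = FALSE)
  }))

  cells <- expand.grid(fusion = fusions, single = singles,
                       stringsAsFactors = FALSE)
  tests <- lapply(seq_len(nrow(cells)), function(i)
    delong_test(wide[[cells$fusion[i]]]$pm, wide[[cells$single[i]]]$pm,
                labels))
  comparisons <- data.frame(
    fusion = cells$fusion, single = cells$single,
    delta_auc = vapply(tests, `[[`, numeric(1), "delta_auc"),
    se = vapply(tests, `[[`, numeric(1), "se"),
    ci_lo = vapply(tests, function(t) t$ci95[1], numeric(1)),
    ci_hi = vapply(tests, function(t) t$ci95[2], numeric(1)),
    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  comparisons$corrected_p <- holm_correct(comparisons$p_value)
  structure(list(schemes = schemes, comparisons = comparisons,
                 n_lesions = length(ids), n_malignant = sum(labels)),
            class = "cadx_report")
}

#' @export
print.cadx_report <- function(x, ...) {
  cat(sprintf("CADx report: %d lesions (%d malignant / %d benign)\n\n",
              x$n_lesions, x$n_malignant, x$n_lesions - x$n_malignant))
  s <- x$schemes
  cat("Per-scheme performance (PM aggregated over outer folds):\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf(
      "  %-18s AUC %.3f [%.3f, %.3f]  sens %.3f  spec %.3f  ppv %.3f  npv %.3f\n",
      s$scheme[i], s$auc[i], s$ci_lo[i], s$ci_hi[i], s$sensitivity[i],
      s$specificity[i], s$ppv[i], s$npv[i]))
  cat("\nPaired DeLong comparisons (Holm-corrected):\n")
  cmp <- x$comparisons
  for (i in seq_len(nrow(cmp)))
    cat(sprintf(
      "  %-18s vs %-4s dAUC %+.3f [%+.3f, %+.3f]  p = %.3g  corrected p = %.3g\n",
      cmp$fusion[i], cmp$single[i], cmp$delta_auc[i], cmp$ci_lo[i],
      cmp$ci_hi[i], cmp$p_value[i], cmp$corrected_p[i]))
  invisible(x)
}
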