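# Shared fixtures, built in code at test time.

# A deterministic structured 2D image (blobs + gradient) for registration
# and resampling tests.
structured_image <- function(n = 72, spacing = c(0.7, 0.7)) {
  xx <- outer(seq_len(n), rep(1, n))
  yy <- t(xx)
  px <- exp(-((xx - 0.4 * n)^2 + (yy - 0.55 * n)^2) / (0.02 * n^2)) +
    0.5 * exp(-((xx - 0.7 * n)^2 + (yy - 0.3 * n)^2) / (0.01 * n^2)) +
    0.1 * xx / n
  roi2d(px, spacing, "structured")
}

# Noise-free, variability-free phantom parameters: fully separable classes.
clean_phantom_params <- function(...) {
  phantom_params(noise_sd = 0,
                 enhancement_sd = c(benign = 0, malignant = 0),
                 t2_contrast_sd = c(benign = 0, malignant = 0), ...)
}

# Small cohort on disk, cached per test session.
.small_cohort_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.small_cohort_env$man)) {
    p <- phantom_params(n_patients = 10, malignant_prevalence = 0.6,
                        seed = 77)
    dir <- file.path(tempdir(), "small_cohort")
    .small_cohort_env$man <- generate_cohort(p, dir)
    .small_cohort_env$dir <- dir
    .small_cohort_env$params <- p
  }
  .small_cohort_env
}

# Synthetic feature matrix with a class-dependent mean shift: a stand-in for
# deep features when testing the CV/SVM machinery in isolation.
synthetic_features <- function(n_patients = 40, lesions_per_patient = 2,
                               n_feat = 20, shift = 1.5, prevalence = 0.5,
                               seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_patients)) {
    for (j in seq_len(lesions_per_patient)) {
      lab <- if (stats::runif(1) < prevalence) "malignant" else "benign"
      rows[[length(rows) + 1]] <- list(
        patient_id = sprintf("P%03d", i),
        lesion_id = sprintf("P%03d_L%d", i, j), label = lab)
    }
  }
  meta <- do.call(rbind.data.frame, rows)
  meta[] <- lapply(meta, as.character)
  x <- matrix(stats::rnorm(nrow(meta) * n_feat), nrow(meta), n_feat)
  x[meta$label == "malignant", seq_len(5)] <-
    x[meta$label == "malignant", seq_len(5)] + shift
  rownames(x) <- meta$lesion_id
  colnames(x) <- sprintf("f%04d", seq_len(n_feat))
  list(features = x, meta = meta)
}

# A small hyperparameter grid keeping SVM grid searches fast in unit tests.
small_grid <- function() hyper_grid(10^seq(-3, 0, length.out = 3),
                                    10^seq(-1, 2, length.out = 3))
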