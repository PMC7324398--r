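# Synthetic paired DCE/T2w phantom cohorts with known ground truth.
#
# The generator emulates the class-conditional structure a breast-MRI CADx
# pipeline relies on: lesion-size distributions (lognormal, calibrated to the
# clinical mean/median/range per class), enhancement kinetics (malignant:
# fast uptake then plateau by the second post-contrast point; benign: slower
# persistent uptake), T2w brightness (benign bright, malignant dark relative
# to parenchyma), lobulated malignant shapes, an in-plane resolution mismatch
# between the two sequences, and multiple lesions per patient.

#' Phantom cohort parameters
#'
#' Defaults emulate the clinical cohort the pipeline targets: 78.5%
#' malignant prevalence, ~1.5 lesions per patient, benign/malignant effective
#' diameters with means 8.86 / 17.9 mm (lognormal, truncated to the observed
#' ranges 3.38-42.8 / 3.37-73.7 mm and calibrated so the truncated mean hits
#' the target), DCE in-plane spacing 0.7 mm vs T2w 0.55 mm with 2 mm slices.
#'
#' Enhancement is expressed as a fraction of the pre-contrast parenchyma
#' level. Per-lesion kinetic and T2-contrast variability (`enhancement_sd`,
#' `t2_contrast_sd`) makes each sequence individually imperfect so that the
#' two carry partially independent class signal; set them to zero for
#' fully separable classes.
#'
#' @param n_patients number of patients in the cohort.
#' @param lesions_per_patient_mean mean lesion count per patient (>= 1;
#'   modelled as 1 + Poisson(mean - 1)).
#' @param malignant_prevalence per-lesion probability of the malignant class.
#' @param benign_diameter_mm,malignant_diameter_mm list(mean, median, range)
#'   of the effective-diameter distribution per class, in mm.
#' @param enhancement list with per-class post1/post2 uptake fractions and
#'   the background parenchyma enhancement.
#' @param enhancement_sd per-lesion SD of the post2 uptake fraction, per class.
#' @param t2_contrast per-class lesion-to-parenchyma T2w intensity ratio.
#' @param t2_contrast_sd per-lesion SD of the T2w ratio, per class.
#' @param noise_sd additive Gaussian noise SD (units of the parenchyma level).
#' @param dce_spacing_mm,t2w_spacing_mm voxel spacing (slice, row, col) mm.
#' @param t2w_offset_mm true physical DCE-to-T2w offset (slice, row, col) mm;
#'   nonzero values create the misalignment the registration stage corrects.
#' @param dt_seconds DCE temporal resolution (s).
#' @param seed integer RNG seed driving all cohort randomness.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(n_patients = 80,
                           lesions_per_patient_mean = 1.5,
                           malignant_prevalence = 0.785,
                           benign_diameter_mm = list(mean = 8.86,
                                                     median = 7.33,
                                                     range = c(3.38, 42.8)),
                           malignant_diameter_mm = list(mean = 17.9,
                                                        median = 14.9,
                                                        range = c(3.37, 73.7)),
                           enhancement = list(
                             benign = c(post1 = 0.45, post2 = 0.75),
                             malignant = c(post1 = 1.00, post2 = 1.05),
                             background = 0.08),
                           enhancement_sd = c(benign = 0.15,
                                              malignant = 0.25),
                           t2_contrast = c(benign = 1.8, malignant = 0.65),
                           t2_contrast_sd = c(benign = 0.25,
                                              malignant = 0.12),
                           noise_sd = 0.04,
                           dce_spacing_mm = c(2.0, 0.7, 0.7),
                           t2w_spacing_mm = c(2.0, 0.55, 0.55),
                           t2w_offset_mm = c(0, 0, 0),
                           dt_seconds = 60,
                           seed = 1L) {
  stopifnot(malignant_prevalence > 0 || malignant_prevalence == 0,
            malignant_prevalence >= 0, malignant_prevalence <= 1,
            all(dce_spacing_mm > 0), all(t2w_spacing_mm > 0),
            noise_sd >= 0, n_patients >= 1,
            lesions_per_patient_mean >= 1)
  p <- list(n_patients = as.integer(n_patients),
            lesions_per_patient_mean = lesions_per_patient_mean,
            malignant_prevalence = malignant_prevalence,
            benign_diameter_mm = benign_diameter_mm,
            malignant_diameter_mm = malignant_diameter_mm,
            enhancement = enhancement,
            enhancement_sd = enhancement_sd,
            t2_contrast = t2_contrast,
            t2_contrast_sd = t2_contrast_sd,
            noise_sd = noise_sd,
            dce_spacing_mm = dce_spacing_mm,
            t2w_spacing_mm = t2w_spacing_mm,
            t2w_offset_mm = t2w_offset_mm,
            dt_seconds = dt_seconds,
            seed = as.integer(seed))
  class(p) <- "phantom_params"
  p
}

# Truncated-lognormal sampler calibrated so that E[X | a <= X <= b] equals the
# target mean, with mu fixed at log(median). Calibration is deterministic
# (closed-form truncated moments + uniroot over sigma).
.trunc_lnorm_mean <- function(mu, sigma, a, b) {
  za <- (log(a) - mu) / sigma
  zb <- (log(b) - mu) / sigma
  denom <- stats::pnorm(zb) - stats::pnorm(za)
  exp(mu + sigma^2 / 2) *
    (stats::pnorm(zb - sigma) - stats::pnorm(za - sigma)) / denom
}

.calibrate_diameter <- function(spec) {
  mu <- log(spec$median)
  a <- spec$range[1]; b <- spec$range[2]
  f <- function(s) .trunc_lnorm_mean(mu, s, a, b) - spec$mean
  sigma <- stats::uniroot(f, c(0.05, 1.5), tol = 1e-10)$root
  list(mu = mu, sigma = sigma, a = a, b = b)
}

#' Sample lesion effective diameters
#'
#' Draws from the class-conditional truncated lognormal used by the phantom
#' generator (rejection sampling within the configured range).
#'
#' @param n number of draws.
#' @param spec list(mean, median, range) as in [phantom_params()].
#' @return numeric vector of diameters (mm).
#' @export
sample_diameters <- function(n, spec) {
  cal <- .calibrate_diameter(spec)
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(n, cal$mu, cal$sigma)
    out <- c(out, d[d >= cal$a & d <= cal$b])
  }
  out[seq_len(n)]
}

# Grid sized to hold a lesion of diameter d plus physical margin, with a
# minimum desk-scale footprint.
.phantom_grid <- function(diameter_mm, spacing, margin_mm = 15,
                          min_dim = c(24, 64, 64)) {
  need <- ceiling((diameter_mm + 2 * margin_mm) / spacing)
  pmax(as.integer(need), as.integer(min_dim))
}

# Implicit lesion indicator evaluated on a grid: perturbed ellipsoid, radius
# modulated by low-order even directional harmonics (lobulation).
.lesion_mask_on_grid <- function(dims, spacing, origin, center_mm, semi_mm,
                                 lobes) {
  cs <- lapply(1:3, function(a)
    origin[a] + (seq_len(dims[a]) - 1) * spacing[a] - center_mm[a])
  x <- cs[[1]][slice.index(array(0, dims), 1)]
  y <- cs[[2]][slice.index(array(0, dims), 2)]
  z <- cs[[3]][slice.index(array(0, dims), 3)]
  xs <- x / semi_mm[1]; ys <- y / semi_mm[2]; zs <- z / semi_mm[3]
  r <- sqrt(xs^2 + ys^2 + zs^2)
  r[r == 0] <- 1e-9
  ux <- xs / r; uy <- ys / r; uz <- zs / r
  # degree-2 real harmonics (even => star-shaped, no antipodal asymmetry)
  pert <- lobes[1] * (ux * uy) + lobes[2] * (uy * uz) + lobes[3] * (ux * uz) +
    lobes[4] * (ux^2 - uy^2) + lobes[5] * (3 * uz^2 - 1) / 2
  pert <- pmax(pmin(pert, 0.4), -0.4)
  arr <- array(r <= 1 + pert, dims)
  arr
}

#' Generate one paired DCE/T2w phantom study
#'
#' Builds the pre + two post-contrast DCE volumes and the T2w volume for a
#' single lesion of known class, together with ground-truth masks in both
#' frames. Lesion voxels follow class-conditional enhancement kinetics;
#' benign lesions are T2-bright, malignant T2-dark relative to parenchyma
#' (level 1.0). Malignant shapes are lobulated perturbed ellipsoids, benign
#' ones near-smooth ellipsoids. Uses the current RNG stream; seed externally
#' for determinism.
#'
#' @param params a [phantom_params] object.
#' @param patient_id,lesion_id identifiers.
#' @param class `"benign"` or `"malignant"`.
#' @param diameter_mm optional fixed effective diameter; drawn from the class
#'   distribution when `NULL`.
#' @return list with `record` (a [study_record] holding in-memory volumes)
#'   and `truth` (masks in both frames, class, true offset, diameter).
#' @export
generate_study <- function(params, patient_id, lesion_id, class,
                           diameter_mm = NULL) {
  stopifnot(inherits(params, "phantom_params"),
            class %in% c("benign", "malignant"))
  dspec <- if (class == "benign") params$benign_diameter_mm
           else params$malignant_diameter_mm
  if (is.null(diameter_mm)) diameter_mm <- sample_diameters(1, dspec)

  dce_sp <- params$dce_spacing_mm
  t2_sp <- params$t2w_spacing_mm
  dims <- .phantom_grid(diameter_mm, dce_sp)
  extent <- dims * dce_sp
  if (any(diameter_mm > extent))
    stop("lesion (", round(diameter_mm, 1), " mm) larger than volume extent")
  t2_dims <- pmax(as.integer(round(extent / t2_sp)), 8L)
  origin <- c(0, 0, 0)

  # geometry: jittered centre, volume-preserving anisotropy, lobulation
  center <- extent / 2 + stats::runif(3, -3, 3)
  ratios <- exp(stats::runif(3, log(0.75), log(1.35)))
  ratios <- ratios / prod(ratios)^(1 / 3)
  semi <- (diameter_mm / 2) * ratios
  lobe_amp <- if (class == "malignant") 0.30 else 0.03
  lobes <- stats::runif(5, -lobe_amp, lobe_amp)

  mask_dce <- .lesion_mask_on_grid(dims, dce_sp, origin, center, semi, lobes)
  if (!any(mask_dce))
    stop("lesion (", round(diameter_mm, 1),
         " mm) produced an empty mask at this resolution")
  off <- params$t2w_offset_mm
  mask_t2 <- .lesion_mask_on_grid(t2_dims, t2_sp, origin, center + off, semi,
                                  lobes)

  # class-conditional signal levels for this lesion
  enh <- params$enhancement[[class]]
  # every included lesion enhances visibly above parenchyma (clinically a
  # precondition for being seen and seeded on DCE at all)
  e2 <- max(0.30, enh[["post2"]] +
              stats::rnorm(1, 0, params$enhancement_sd[[class]]))
  e1 <- e2 * enh[["post1"]] / enh[["post2"]]
  t2r <- max(0.05, params$t2_contrast[[class]] +
               stats::rnorm(1, 0, params$t2_contrast_sd[[class]]))
  bg <- params$enhancement$background

  noise <- function(d) if (params$noise_sd > 0)
    array(stats::rnorm(prod(d), 0, params$noise_sd), d) else array(0, d)

  base <- array(1, dims)
  pre <- base + noise(dims)
  post1 <- base + bg + (e1 - bg) * mask_dce + noise(dims)
  post2 <- base + bg + (e2 - bg) * mask_dce + noise(dims)
  t2w <- array(1, t2_dims) + (t2r - 1) * mask_t2 + noise(t2_dims)

  vol <- function(a, sp, tag) image_volume(a, sp, origin, tag)
  series <- dynamic_series(vol(pre, dce_sp, "dce_pre"),
                           list(vol(post1, dce_sp, "dce_post1"),
                                vol(post2, dce_sp, "dce_post2")),
                           dt_seconds = params$dt_seconds)

  seed_pt <- .mask_centroid_voxel(mask_dce)
  rec <- study_record(patient_id, lesion_id, class, seed_pt,
                      dce = series, t2w = vol(t2w, t2_sp, "t2w"))
  truth <- list(mask_dce = mask_dce, mask_t2w = mask_t2, class = class,
                offset_mm = off, diameter_mm = diameter_mm,
                center_mm = center)
  list(record = rec, truth = truth)
}

# Centroid of a mask snapped to the nearest in-mask voxel, 0-based.
.mask_centroid_voxel <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  d2 <- rowSums(sweep(idx, 2, ctr)^2)
  as.integer(idx[which.min(d2), ]) - 1L
}

#' Generate a phantom cohort on disk
#'
#' Draws patients, per-patient lesion counts, per-lesion classes and sizes,
#' writes every volume as NIfTI plus a ground-truth sidecar, and writes the
#' cohort manifest CSV. All randomness derives from `params$seed`, so equal
#' seeds give byte-identical manifests.
#'
#' @param params a [phantom_params] object.
#' @param out_dir writable output directory (created if needed).
#' @return path to the manifest CSV; ground truth is in `ground_truth.json`
#'   and per-lesion mask volumes alongside it.
#' @export
generate_cohort <- function(params, out_dir) {
  stopifnot(inherits(params, "phantom_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(params$seed)

  rows <- list(); truths <- list()
  for (ip in seq_len(params$n_patients)) {
    pid <- sprintf("P%03d", ip)
    n_les <- 1L + stats::rpois(1, params$lesions_per_patient_mean - 1)
    for (il in seq_len(n_les)) {
      lid <- sprintf("%s_L%d", pid, il)
      cls <- if (stats::runif(1) < params$malignant_prevalence) "malignant"
             else "benign"
      st <- generate_study(params, pid, lid, cls)
      stem <- lid
      files <- c(dce_pre = paste0(stem, "_pre.nii.gz"),
                 dce_post1 = paste0(stem, "_post1.nii.gz"),
                 dce_post2 = paste0(stem, "_post2.nii.gz"),
                 t2w = paste0(stem, "_t2w.nii.gz"))
      write_volume(st$record$dce$pre, file.path(out_dir, files["dce_pre"]),
                   datatype = "float")
      write_volume(st$record$dce$post[[1]],
                   file.path(out_dir, files["dce_post1"]), datatype = "float")
      write_volume(st$record$dce$post[[2]],
                   file.path(out_dir, files["dce_post2"]), datatype = "float")
      write_volume(st$record$t2w, file.path(out_dir, files["t2w"]),
                   datatype = "float")
      mask_file <- paste0(stem, "_mask_dce.nii.gz")
      write_volume(image_volume(st$truth$mask_dce + 0, params$dce_spacing_mm),
                   file.path(out_dir, mask_file), datatype = "float")
      mask_t2_file <- paste0(stem, "_mask_t2w.nii.gz")
      write_volume(image_volume(st$truth$mask_t2w + 0, params$t2w_spacing_mm),
                   file.path(out_dir, mask_t2_file), datatype = "float")
      sp <- st$record$seed_point
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, lesion_id = lid, label = cls,
        seed_slice = sp[1], seed_row = sp[2], seed_col = sp[3],
        dce_pre = files[["dce_pre"]], dce_post1 = files[["dce_post1"]],
        dce_post2 = files[["dce_post2"]], t2w = files[["t2w"]],
        stringsAsFactors = FALSE)
      truths[[lid]] <- list(class = cls,
                            diameter_mm = st$truth$diameter_mm,
                            offset_mm = st$truth$offset_mm,
                            center_mm = st$truth$center_mm,
                            mask_dce = mask_file, mask_t2w = mask_t2_file)
    }
  }
  manifest <- do.call(rbind, rows)
  man_path <- file.path(out_dir, "manifest.csv")
  write_manifest(manifest, man_path)
  jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  man_path
}

#' Read a cohort's ground-truth sidecar
#'
#' @param out_dir cohort directory written by [generate_cohort()].
#' @return named list per lesion (class, diameter, offset, mask paths).
#' @export
read_ground_truth <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "ground_truth.json"),
                      simplifyVector = TRUE)
}
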