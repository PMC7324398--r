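# End-to-end orchestration: phantom simulation -> segmentation -> ROI
# construction (optionally with rigid inter-sequence registration) ->
# multi-depth deep features for the three input variants -> five
# classification schemes -> comparison report. Every stage is persisted so
# intermediate products can be inspected, and all randomness flows from the
# config seeds.

#' Pipeline configuration
#'
#' One structured object holding every stage's parameters; it is echoed into
#' the run log and hashed into the provenance file, so two runs with equal
#' configs are identical.
#'
#' @param phantom a [phantom_params] object (used by [run_simulate()]).
#' @param fcm an [fcm_params] object.
#' @param margin_px ROI parenchyma margin per side in pixels.
#' @param registration logical: register the T2w centre slice to the
#'   corresponding DCE slice before cropping.
#' @param backbone_weights `"random"` or an RDS path (see [load_backbone()]).
#' @param backbone_seed seed for the random-weight backbone.
#' @param cv_seed outer/inner CV split seed.
#' @param cv_tol allowed per-fold prevalence deviation for the outer CV plan
#'   (see [make_cv_plan()]); `Inf` accepts the best-balanced plan found,
#'   which small cohorts may require.
#' @param grid a [hyper_grid].
#' @param pca_var retained-variance fraction of the training-fold PCA.
#' @param schemes schemes to train (classifier fusion is derived from the
#'   two single-sequence PM tables).
#' @param bootstrap_B bootstrap samples for the per-scheme CIs.
#' @param equivalence_margin AUC equivalence margin.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(phantom = phantom_params(),
                            fcm = fcm_params(),
                            margin_px = 3L,
                            registration = FALSE,
                            backbone_weights = "random",
                            backbone_seed = 1L,
                            cv_seed = 1L,
                            cv_tol = 0.05,
                            grid = hyper_grid(),
                            pca_var = 0.95,
                            schemes = c("dce", "t2w", "image_fusion",
                                        "feature_fusion",
                                        "classifier_fusion"),
                            bootstrap_B = 2000L,
                            equivalence_margin = 0.05) {
  structure(list(phantom = phantom, fcm = fcm,
                 margin_px = as.integer(margin_px),
                 registration = isTRUE(registration),
                 backbone_weights = backbone_weights,
                 backbone_seed = as.integer(backbone_seed),
                 cv_seed = as.integer(cv_seed), cv_tol = cv_tol,
                 grid = grid,
                 pca_var = pca_var, schemes = schemes,
                 bootstrap_B = as.integer(bootstrap_B),
                 equivalence_margin = equivalence_margin),
            class = "pipeline_config")
}

#' Simulate a phantom cohort
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory for volumes + manifest.
#' @return manifest path.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  man <- generate_cohort(config$phantom, out_dir)
  n <- nrow(utils::read.csv(man))
  message(sprintf("simulated cohort: %d lesions (seed %d) -> %s",
                  n, config$phantom$seed, man))
  man
}

#' Build the per-lesion ROI inputs
#'
#' For one study record: segment the lesion on the second post-contrast
#' subtraction volume, build the DCE subtraction MIP and its lesion
#' footprint, transfer the mask to the T2w frame, select and
#' resolution-match the T2w centre slice (optionally registering it to the
#' corresponding DCE slice), crop the co-located ROI pair and compose the
#' RGB fusion ROI.
#'
#' @param rec a [study_record] (volumes loaded on demand).
#' @param config a [pipeline_config].
#' @return list(`pair` (`roi_pair`), `fusion` (`fusion_roi`), `mask`
#'   (`lesion_mask`), `transform` (`rigid_transform2d` or NULL), `geometry`
#'   (box/shift log entry)).
#' @export
build_lesion_rois <- function(rec, config = pipeline_config()) {
  rec <- load_study(rec)
  sub <- subtraction_volume(rec$dce, 2L)
  mask <- fcm_segment(sub, rec$seed_point, config$fcm)

  dce_mip <- mip(sub)
  fp_dce <- apply(mask$mask, c(2, 3), any)

  t2w <- rec$t2w
  mask_t2 <- mask_to_frame(mask$mask, sub$spacing, sub$origin,
                           dim(t2w$voxels), t2w$spacing, t2w$origin)
  if (!any(mask_t2))
    stop("lesion mask transfers to an empty T2w-frame mask")
  cs <- select_center_slice(t2w, mask_t2)
  t2_res <- resample_inplane(cs$image, dce_mip$pixel_spacing_mm)
  fp_t2 <- resample_footprint(cs$footprint, t2w$spacing[2:3],
                              dce_mip$pixel_spacing_mm)

  transform <- NULL
  if (config$registration) {
    # the DCE slice whose physical position matches the T2w centre slice
    z_mm <- t2w$origin[1] + cs$slice * t2w$spacing[1]
    k <- round((z_mm - sub$origin[1]) / sub$spacing[1]) + 1
    k <- min(max(k, 1), dim(sub$voxels)[1])
    fixed <- roi2d(sub$voxels[k, , ], sub$spacing[2:3], "dce_slice")
    transform <- register_rigid(t2_res, fixed)
    t2_res <- apply_transform(t2_res, transform)
    # footprint follows the same rigid map (thresholded back to binary)
    fp_t2r <- apply_transform(roi2d(fp_t2 + 0, dce_mip$pixel_spacing_mm),
                              transform)
    fp_t2 <- fp_t2r$pixels > 0.5
    if (!any(fp_t2))
      stop("registered T2w footprint is empty")
  }

  pair <- crop_pair(dce_mip, t2_res, fp_dce, fp_t2, config$margin_px)
  fusion <- make_fusion(pair)
  list(pair = pair, fusion = fusion, mask = mask, transform = transform,
       geometry = list(lesion_id = rec$lesion_id, side_px = pair$side_px,
                       box_dce = pair$dce$box, box_t2w = pair$t2w$box,
                       center_slice_t2w = cs$slice,
                       registered = config$registration))
}

#' Run the full classification experiment
#'
#' Executes every stage on a cohort manifest and returns the five-scheme
#' comparison report. Intermediates (feature tables, PM table, geometry log,
#' provenance) are persisted under `out_dir`.
#'
#' @param manifest path to a cohort manifest CSV.
#' @param config a [pipeline_config].
#' @param out_dir directory for persisted intermediates (default: alongside
#'   the manifest).
#' @return list(`report` (`cadx_report`), `pm` (`pm_table`), `features`
#'   (named list of matrices), `geometry`).
#' @export
run_full <- function(manifest, config = pipeline_config(),
                     out_dir = file.path(dirname(manifest), "results")) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- load_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("run_full: %d lesions, registration %s",
                  length(records), if (config$registration) "on" else "off"))

  rois_dce <- list(); rois_t2w <- list(); rois_fus <- list()
  geometry <- list()
  for (rec in records) {
    r <- tryCatch(build_lesion_rois(rec, config),
                  error = function(e)
                    stop("stage roi failed for lesion ", rec$lesion_id, ": ",
                         conditionMessage(e)))
    rois_dce[[rec$lesion_id]] <- r$pair$dce$pixels
    rois_t2w[[rec$lesion_id]] <- r$pair$t2w$pixels
    rois_fus[[rec$lesion_id]] <- r$fusion
    geometry[[rec$lesion_id]] <- r$geometry
  }
  jsonlite::write_json(geometry, file.path(out_dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)

  backbone <- load_backbone(config$backbone_weights, config$backbone_seed)
  feats <- list(dce = featurize_cohort(rois_dce, backbone, "dce"),
                t2w = featurize_cohort(rois_t2w, backbone, "t2w"),
                image_fusion = featurize_cohort(rois_fus, backbone,
                                                "image_fusion"))
  feats$feature_fusion <- cbind(feats$dce, feats$t2w)
  colnames(feats$feature_fusion) <-
    sprintf("f%04d", seq_len(ncol(feats$feature_fusion)))
  for (s in names(feats))
    utils::write.csv(data.frame(lesion_id = rownames(feats[[s]]),
                                feats[[s]], check.names = FALSE),
                     file.path(out_dir, paste0("features_", s, ".csv")),
                     row.names = FALSE)

  meta <- data.frame(
    lesion_id = vapply(records, `[[`, character(1), "lesion_id"),
    patient_id = vapply(records, `[[`, character(1), "patient_id"),
    label = vapply(records, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  plan <- make_cv_plan(meta, k = 5L, seed = config$cv_seed,
                       tol = config$cv_tol)

  trained <- intersect(config$schemes,
                       c("dce", "t2w", "image_fusion", "feature_fusion"))
  pms <- lapply(trained, function(s)
    train_eval_scheme(feats[[s]], meta, plan, config$grid, s,
                      config$pca_var))
  names(pms) <- trained
  if ("classifier_fusion" %in% config$schemes) {
    if (!all(c("dce", "t2w") %in% trained))
      stop("classifier_fusion needs the dce and t2w schemes")
    pms$classifier_fusion <- classifier_fusion(pms$dce, pms$t2w)
  }
  pm <- do.call(rbind, pms)
  rownames(pm) <- NULL
  class(pm) <- c("pm_table", "data.frame")
  utils::write.csv(pm, file.path(out_dir, "pm_table.csv"), row.names = FALSE)

  report <- NULL
  if (length(unique(pm$scheme)) == 5L) {
    report <- compare_all(pm, B = config$bootstrap_B, seed = config$cv_seed)
    jsonlite::write_json(report[c("schemes", "comparisons")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  prov <- list(config_hash = .config_hash(config),
               n_lesions = nrow(meta), schemes = unique(pm$scheme),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  list(report = report, pm = pm, features = feats, geometry = geometry,
       plan = plan)
}

.config_hash <- function(config) {
  s <- jsonlite::serializeJSON(config[setdiff(names(config), "grid")])
  # small deterministic fingerprint without extra dependencies
  sum(utf8ToInt(as.character(s)) * seq_along(utf8ToInt(as.character(s)))) %%
    .Machine$integer.max
}
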