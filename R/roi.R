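# Region-of-interest construction: the three 2D classifier inputs per lesion.
#
# DCE branch: second post-contrast subtraction volume -> transverse maximum
# intensity projection (MIP). T2w branch: slice with the largest lesion area,
# bicubic-resampled to the DCE in-plane resolution. Both are cropped with a
# common square box (lesion max dimension + 3-pixel parenchyma margin per
# side), each centred on its own lesion footprint; the fusion composite puts
# DCE in red, T2w in green and leaves blue blank.

#' Subtraction volume
#'
#' Voxelwise post-contrast minus pre-contrast enhancement volume.
#'
#' @param series a [dynamic_series].
#' @param timepoint index of the post-contrast volume (default 2, the second
#'   post-contrast point: the initial enhancement phase with diagnostic
#'   value).
#' @return An [image_volume] with inherited spacing.
#' @export
subtraction_volume <- function(series, timepoint = 2L) {
  stopifnot(inherits(series, "dynamic_series"))
  if (timepoint < 1L || timepoint > length(series$post))
    stop("timepoint ", timepoint, " outside the ", length(series$post),
         " post-contrast volumes")
  post <- series$post[[timepoint]]
  if (!identical(dim(post$voxels), dim(series$pre$voxels)))
    stop("post/pre volume shape mismatch")
  image_volume(post$voxels - series$pre$voxels, post$spacing,
               origin = post$origin,
               series_tag = sprintf("sub_post%d", timepoint))
}

#' Maximum intensity projection
#'
#' Pixelwise maximum along the slice axis (transverse MIP), collapsing the
#' volume to a 2D image at the in-plane spacing.
#'
#' @param vol an [image_volume] with at least one slice.
#' @return A `roi2d`: list(pixels, pixel_spacing_mm, source_tag).
#' @export
mip <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  px <- apply(vol$voxels, c(2, 3), max)
  roi2d(px, vol$spacing[2:3], "dce_mip")
}

#' Construct a 2D ROI image
#'
#' @param pixels 2D numeric matrix (row, col).
#' @param pixel_spacing_mm length-2 spacing (row, col) in mm.
#' @param source_tag provenance tag, e.g. `"dce_mip"` or `"t2w_center"`.
#' @param box optional (row0, col0, row1, col1) half-open crop box (0-based)
#'   in the source image frame.
#' @return A `roi2d` object.
#' @export
roi2d <- function(pixels, pixel_spacing_mm, source_tag = "", box = NULL) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            length(pixel_spacing_mm) == 2L, all(pixel_spacing_mm > 0))
  structure(list(pixels = pixels,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 source_tag = source_tag, box = box),
            class = "roi2d")
}

#' Select the T2w centre slice
#'
#' The representative T2w slice is the one containing the largest lesion
#' area according to the (frame-transferred) segmentation; ties go to the
#' lowest slice index.
#'
#' @param t2w an [image_volume].
#' @param mask_in_t2w logical 3D array on the T2w grid (nonempty).
#' @return list(`slice` 0-based index, `image` a `roi2d` of that slice,
#'   `footprint` the in-slice lesion mask).
#' @export
select_center_slice <- function(t2w, mask_in_t2w) {
  stopifnot(inherits(t2w, "image_volume"),
            identical(dim(mask_in_t2w), dim(t2w$voxels)))
  areas <- apply(mask_in_t2w, 1, sum)
  if (sum(areas) == 0) stop("empty lesion mask: no centre slice")
  k <- which.max(areas)  # which.max returns the first (lowest) maximiser
  list(slice = k - 1L,
       image = roi2d(t2w$voxels[k, , ], t2w$spacing[2:3], "t2w_center"),
       footprint = mask_in_t2w[k, , ])
}

# Catmull-Rom cubic convolution kernel (a = -0.5), the classic bicubic
# interpolation kernel; reproduces linear ramps exactly.
.cubic_kernel <- function(s, a = -0.5) {
  s <- abs(s)
  ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
         ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
}

# Row-sampling matrix for 1D cubic convolution from n_src samples at spacing
# sp_src onto the grid implied by sp_dst, with centre-aligned physical
# extents and edge clamping. Rows sum to 1 exactly (renormalised), so
# constants are reproduced bit-for-bit.
.cubic_weights <- function(n_src, sp_src, sp_dst) {
  n_dst <- max(1L, as.integer(round(n_src * sp_src / sp_dst)))
  pos <- ((seq_len(n_dst) - 0.5) * sp_dst) / sp_src - 0.5  # 0-based src coords
  w <- matrix(0, n_dst, n_src)
  base <- floor(pos)
  for (t in -1:2) {
    idx <- base + t
    wt <- .cubic_kernel(pos - idx)
    idx <- pmin(pmax(idx, 0), n_src - 1L)  # clamp at borders
    w[cbind(seq_len(n_dst), idx + 1L)] <-
      w[cbind(seq_len(n_dst), idx + 1L)] + wt
  }
  w / rowSums(w)
}

#' Resample a 2D image in-plane
#'
#' Bicubic (Catmull-Rom) interpolation onto the grid of the target pixel
#' spacing, preserving the physical extent within one output pixel. Used to
#' bring the T2w centre slice to the DCE in-plane resolution.
#'
#' @param img a `roi2d` (or plain matrix with `spacing` supplied).
#' @param target_spacing length-2 target (row, col) spacing in mm, or a
#'   scalar for isotropic targets.
#' @param spacing source spacing, required when `img` is a bare matrix.
#' @return A `roi2d` at the target spacing.
#' @export
resample_inplane <- function(img, target_spacing, spacing = NULL) {
  if (inherits(img, "roi2d")) {
    px <- img$pixels; spacing <- img$pixel_spacing_mm; tag <- img$source_tag
  } else {
    px <- img; tag <- ""
    if (is.null(spacing)) stop("spacing required for a bare matrix")
  }
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 2)
  stopifnot(all(target_spacing > 0), all(spacing > 0))
  wr <- .cubic_weights(nrow(px), spacing[1], target_spacing[1])
  wc <- .cubic_weights(ncol(px), spacing[2], target_spacing[2])
  roi2d(wr %*% px %*% t(wc), target_spacing, tag)
}

#' Resample a binary 2D footprint
#'
#' Nearest-neighbour companion to [resample_inplane()] for lesion
#' footprints, aligned to the same output grid.
#'
#' @param fp logical matrix.
#' @param spacing,target_spacing as in [resample_inplane()].
#' @return logical matrix on the target grid.
#' @export
resample_footprint <- function(fp, spacing, target_spacing) {
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 2)
  map1 <- .nn_map(nrow(fp), spacing[1], target_spacing[1])
  map2 <- .nn_map(ncol(fp), spacing[2], target_spacing[2])
  fp[map1, map2, drop = FALSE]
}

.nn_map <- function(n_src, sp_src, sp_dst) {
  n_dst <- max(1L, as.integer(round(n_src * sp_src / sp_dst)))
  pos <- ((seq_len(n_dst) - 0.5) * sp_dst) / sp_src - 0.5
  pmin(pmax(as.integer(round(pos)), 0L), n_src - 1L) + 1L
}

#' Square ROI box around a lesion footprint
#'
#' Box side L = max(footprint bounding-box height, width) + 2 * margin,
#' centred on the bounding-box centre. Near image borders the box is shifted
#' (never shrunk) to stay inside; it is an error for L to exceed the image.
#'
#' @param mask_2d logical matrix: lesion footprint in the 2D frame.
#' @param margin_px parenchyma margin per side, in pixels (default 3).
#' @param img_dim image (rows, cols); defaults to `dim(mask_2d)`.
#' @return integer (row0, col0, row1, col1), half-open, 0-based.
#' @export
roi_box <- function(mask_2d, margin_px = 3L, img_dim = dim(mask_2d)) {
  idx <- which(mask_2d, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty lesion footprint")
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  L <- max(diff(rr), diff(cc)) + 1L + 2L * as.integer(margin_px)
  if (L > min(img_dim))
    stop("ROI side ", L, " px exceeds image extent ",
         paste(img_dim, collapse = "x"))
  ctr <- c(mean(rr), mean(cc)) - 1      # 0-based footprint centre
  r0 <- as.integer(round(ctr[1] - (L - 1) / 2))
  c0 <- as.integer(round(ctr[2] - (L - 1) / 2))
  r0 <- min(max(r0, 0L), img_dim[1] - L)   # shift, never shrink
  c0 <- min(max(c0, 0L), img_dim[2] - L)
  c(r0, c0, r0 + L, c0 + L)
}

#' Crop co-located DCE/T2w ROIs
#'
#' Applies one common box side L (the larger of the two footprints' sides for
#' the given margin) to both resolution-matched images, with each box centred
#' on its own footprint — the coordinate "shift" that keeps both crops at the
#' same location relative to the lesion.
#'
#' @param dce_mip `roi2d`: the subtraction MIP.
#' @param t2w_center `roi2d`: the resolution-matched T2w centre slice.
#' @param fp_dce,fp_t2w logical lesion footprints in the two frames.
#' @param margin_px parenchyma margin per side (default 3).
#' @return A `roi_pair`: list(dce, t2w, side_px).
#' @export
crop_pair <- function(dce_mip, t2w_center, fp_dce, fp_t2w, margin_px = 3L) {
  stopifnot(inherits(dce_mip, "roi2d"), inherits(t2w_center, "roi2d"))
  if (max(abs(dce_mip$pixel_spacing_mm - t2w_center$pixel_spacing_mm)) > 1e-6)
    stop("crop_pair requires resolution-matched images; resample first")
  side_of <- function(fp) {
    idx <- which(fp, arr.ind = TRUE)
    max(diff(range(idx[, 1])), diff(range(idx[, 2]))) + 1L +
      2L * as.integer(margin_px)
  }
  if (!any(fp_dce)) stop("crop failed for sequence dce: empty footprint")
  if (!any(fp_t2w)) stop("crop failed for sequence t2w: empty footprint")
  L <- max(side_of(fp_dce), side_of(fp_t2w))
  crop1 <- function(img, fp, tag) {
    box <- .box_with_side(fp, L, dim(img$pixels), tag)
    roi2d(img$pixels[(box[1] + 1):box[3], (box[2] + 1):box[4]],
          img$pixel_spacing_mm, img$source_tag, box = box)
  }
  structure(list(dce = crop1(dce_mip, fp_dce, "dce"),
                 t2w = crop1(t2w_center, fp_t2w, "t2w"),
                 side_px = L),
            class = "roi_pair")
}

.box_with_side <- function(fp, L, img_dim, tag) {
  idx <- which(fp, arr.ind = TRUE)
  if (L > min(img_dim))
    stop("crop failed for sequence ", tag, ": ROI side ", L,
         " px exceeds image ", paste(img_dim, collapse = "x"))
  ctr <- c(mean(range(idx[, 1])), mean(range(idx[, 2]))) - 1
  r0 <- min(max(as.integer(round(ctr[1] - (L - 1) / 2)), 0L),
            img_dim[1] - L)
  c0 <- min(max(as.integer(round(ctr[2] - (L - 1) / 2)), 0L),
            img_dim[2] - L)
  c(r0, c0, r0 + L, c0 + L)
}

#' Min-max rescale an image to [0, 1]
#'
#' @param px numeric matrix; a constant image maps to all zeros.
#' @return rescaled matrix.
#' @export
rescale01 <- function(px) {
  rng <- range(px)
  if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
}

#' Build the RGB fusion composite
#'
#' DCE ROI into the red channel, T2w ROI into the green channel, blue left
#' blank; each non-blank channel independently min-max rescaled to [0, 1].
#'
#' @param pair a `roi_pair` from [crop_pair()] (equal shapes enforced).
#' @return A `fusion_roi`: H x W x 3 array with `channel_map` attribute
#'   `c(red = "dce_mip", green = "t2w_center", blue = "blank")`.
#' @export
make_fusion <- function(pair) {
  stopifnot(inherits(pair, "roi_pair"))
  r <- pair$dce$pixels; g <- pair$t2w$pixels
  if (!identical(dim(r), dim(g)))
    stop("fusion requires equal ROI shapes, got ",
         paste(dim(r), collapse = "x"), " vs ", paste(dim(g), collapse = "x"))
  arr <- array(0, c(dim(r), 3L))
  arr[, , 1] <- rescale01(r)
  arr[, , 2] <- rescale01(g)
  structure(arr,
            channel_map = c(red = "dce_mip", green = "t2w_center",
                            blue = "blank"),
            class = "fusion_roi")
}
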