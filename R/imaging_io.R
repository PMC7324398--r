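#' @keywords internal
"_PACKAGE"

# Canonical axis order throughout the package is (slice, row, col), 0-based
# voxel indices at user-facing boundaries. Physical position of voxel
# (i, j, k) is origin + c(i, j, k) * spacing, in mm.

#' Construct an in-memory image volume
#'
#' The canonical imaging container: a 3D scalar voxel grid with anisotropic
#' voxel spacing in mm, a physical origin, and a free-text series tag. Axis
#' order is (slice, row, col) everywhere in the package.
#'
#' @param voxels 3D numeric array, dimension (slice, row, col).
#' @param spacing numeric length-3, voxel spacing in mm (slice, row, col);
#'   all components must be positive.
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @param series_tag free-text label for the series.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         series_tag = "") {
  voxels <- unclass(voxels)
  attributes(voxels) <- list(dim = dim(voxels))
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array, got ", length(dim(voxels)), " dims")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values, got: ",
         paste(spacing, collapse = ", "))
  if (!all(is.finite(voxels)))
    stop("voxel array contains non-finite values")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), series_tag = series_tag),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  dim %s  spacing %s mm\n",
              if (nzchar(x$series_tag)) x$series_tag else "(untagged)",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' Construct a dynamic contrast-enhanced series
#'
#' One pre-contrast volume plus at least two post-contrast volumes acquired
#' at a fixed interval (clinically 60 s). All member volumes must share shape
#' and spacing.
#'
#' @param pre pre-contrast [image_volume].
#' @param post list of post-contrast [image_volume]s (length >= 2), in
#'   acquisition order.
#' @param dt_seconds acquisition interval in seconds (> 0).
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(pre, post, dt_seconds = 60) {
  stopifnot(inherits(pre, "image_volume"))
  if (!is.list(post) || length(post) < 2L)
    stop("a dynamic series needs at least 2 post-contrast volumes")
  for (p in post) {
    stopifnot(inherits(p, "image_volume"))
    if (!identical(dim(p$voxels), dim(pre$voxels)))
      stop("post-contrast volume shape differs from pre-contrast")
    if (max(abs(p$spacing - pre$spacing)) > 1e-6)
      stop("post-contrast volume spacing differs from pre-contrast")
  }
  if (!is.finite(dt_seconds) || dt_seconds <= 0)
    stop("dt_seconds must be positive")
  structure(list(pre = pre, post = post, dt_seconds = dt_seconds),
            class = "dynamic_series")
}

#' Construct a study record for one lesion
#'
#' Ties together a lesion's DCE series, T2w volume, diagnostic label, seed
#' point and patient linkage. Several lesions may share a `patient_id`; that
#' linkage drives patient-grouped cross-validation.
#'
#' @param patient_id,lesion_id identifiers (coerced to character).
#' @param label `"benign"` or `"malignant"`; anything else is rejected,
#'   mirroring the exclusion of lesions without a clear benign/malignant
#'   allocation.
#' @param seed_point integer length-3, 0-based (slice, row, col) voxel index
#'   into the DCE grid.
#' @param dce a [dynamic_series], or a named list of file paths
#'   (`pre`, `post` character vector) for lazy loading.
#' @param t2w an [image_volume] or a file path.
#' @param dce_dim optional DCE grid dimension, required to validate
#'   `seed_point` when `dce` is given as paths.
#' @return An object of class `study_record`.
#' @export
study_record <- function(patient_id, lesion_id, label, seed_point, dce, t2w,
                         dce_dim = NULL) {
  if (!label %in% c("benign", "malignant"))
    stop("label must be 'benign' or 'malignant', got '", label, "'")
  seed_point <- as.integer(seed_point)
  if (length(seed_point) != 3L || anyNA(seed_point))
    stop("seed_point must be 3 integer voxel indices")
  if (inherits(dce, "dynamic_series")) dce_dim <- dim(dce$pre$voxels)
  if (is.null(dce_dim))
    stop("dce_dim required when dce is supplied as paths")
  if (any(seed_point < 0L) || any(seed_point >= dce_dim))
    stop("seed_point (", paste(seed_point, collapse = ","),
         ") lies outside the DCE grid ", paste(dce_dim, collapse = "x"))
  structure(list(patient_id = as.character(patient_id),
                 lesion_id = as.character(lesion_id),
                 label = label, seed_point = seed_point,
                 dce = dce, t2w = t2w, dce_dim = as.integer(dce_dim)),
            class = "study_record")
}

#' Read a volumetric image from disk
#'
#' Reads a NIfTI-1 volume into an [image_volume]. Voxel spacing is taken from
#' the header and validated: zero, negative or non-finite spacing is a hard
#' error, never silently defaulted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param series_tag optional tag attached to the returned volume.
#' @return An [image_volume].
#' @export
read_volume <- function(path, series_tag = "") {
  if (!file.exists(path))
    stop("cannot read volume: file does not exist: ", path)
  raw_sp <- .read_nifti_pixdim_raw(path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("unreadable volume file '", path, "': ",
                         conditionMessage(e)))
  vox <- as.array(img)
  if (length(dim(vox)) != 3L)
    stop("expected a 3D volume in '", path, "', got dims ",
         paste(dim(vox), collapse = "x"))
  sp <- RNifti::pixdim(img)[1:3]
  if (!is.null(raw_sp) && (any(!is.finite(raw_sp)) || any(raw_sp <= 0)))
    stop("invalid voxel spacing in header of '", path, "': ",
         paste(raw_sp, collapse = ", "))
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("invalid voxel spacing in header of '", path, "': ",
         paste(sp, collapse = ", "))
  hdr <- RNifti::niftiHeader(img)
  org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  if (any(!is.finite(org))) org <- c(0, 0, 0)
  if (!all(is.finite(vox)))
    stop("volume '", path, "' contains non-finite voxels")
  image_volume(vox, sp, origin = org, series_tag = series_tag)
}

# Raw pixdim[1..3] straight from the NIfTI-1 header bytes, because the nifti
# library canonicalises signs on load and a corrupt negative spacing would
# otherwise pass unnoticed. Returns NULL if the file is not NIfTI-1.
.read_nifti_pixdim_raw <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  if (length(hdr) < 348) return(NULL)
  sizeof <- readBin(hdr[1:4], "integer", size = 4, endian = "little")
  endian <- "little"
  if (sizeof != 348L) {
    sizeof <- readBin(hdr[1:4], "integer", size = 4, endian = "big")
    if (sizeof != 348L) return(NULL)
    endian <- "big"
  }
  readBin(hdr[81:92], "numeric", n = 3, size = 4, endian = endian)
}

#' Write a volumetric image to disk
#'
#' Writes an [image_volume] as NIfTI-1. With `datatype = "double"` the voxel
#' values round-trip bit-compatibly through [read_volume()].
#'
#' @param vol an [image_volume].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @param datatype on-disk storage type, `"double"` (lossless) or `"float"`
#'   (half the size; used for bulk phantom cohorts).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("double", "float")) {
  stopifnot(inherits(vol, "image_volume"))
  datatype <- match.arg(datatype)
  if (!dir.exists(dirname(path)))
    stop("cannot write volume: directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::asNifti(img, reference = list(
    qoffset_x = vol$origin[1], qoffset_y = vol$origin[2],
    qoffset_z = vol$origin[3], qform_code = 1L))
  ok <- tryCatch({RNifti::writeNifti(img, path, datatype = datatype); TRUE},
                 error = function(e)
                   stop("failed to write volume to '", path, "': ",
                        conditionMessage(e)))
  invisible(path)
}

#' Load a cohort manifest
#'
#' Reads the cohort CSV (columns `patient_id, lesion_id, label, seed_slice,
#' seed_row, seed_col, dce_pre, dce_post1, dce_post2[, dce_post3...], t2w`)
#' and returns one [study_record] per row. File paths are resolved relative
#' to the manifest's directory. Every row is validated (label, file
#' existence, seed inside the DCE grid); any failure aborts the load with a
#' per-row error report.
#'
#' @param path path to the manifest CSV.
#' @param eager if `TRUE`, volumes are loaded into memory; the default keeps
#'   file paths for on-demand loading via [load_study()].
#' @return list of [study_record]s.
#' @export
load_manifest <- function(path, eager = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("patient_id", "lesion_id", "label", "seed_slice", "seed_row",
                "seed_col", "dce_pre", "dce_post1", "dce_post2", "t2w")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("manifest is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("manifest '", path, "' is empty")
    return(list())
  }
  base <- dirname(normalizePath(path))
  post_cols <- grep("^dce_post[0-9]+$", names(tab), value = TRUE)
  post_cols <- post_cols[order(as.integer(sub("dce_post", "", post_cols)))]
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))

  errors <- character(0)
  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    fail <- function(msg)
      errors[[length(errors) + 1L]] <<- sprintf("row %d (lesion %s): %s",
                                                i, row$lesion_id, msg)
    if (!row$label %in% c("benign", "malignant")) {
      fail(paste0("unknown label '", row$label, "'"))
      next
    }
    paths <- resolve(unlist(row[c("dce_pre", post_cols, "t2w")],
                            use.names = FALSE))
    gone <- paths[!file.exists(paths)]
    if (length(gone)) {
      fail(paste("missing file(s):", paste(gone, collapse = ", ")))
      next
    }
    seed <- suppressWarnings(as.integer(
      row[c("seed_slice", "seed_row", "seed_col")]))
    hdr <- RNifti::niftiHeader(paths[1])
    dce_dim <- hdr$dim[2:4]
    if (anyNA(seed) || any(seed < 0L) || any(seed >= dce_dim)) {
      fail(paste0("seed (", paste(seed, collapse = ","),
                  ") outside DCE grid ", paste(dce_dim, collapse = "x")))
      next
    }
    npost <- length(post_cols)
    dce <- list(pre = paths[1], post = paths[2:(1 + npost)])
    records[[i]] <- study_record(row$patient_id, row$lesion_id, row$label,
                                 seed, dce = dce, t2w = paths[2 + npost],
                                 dce_dim = dce_dim)
  }
  if (length(errors))
    stop("manifest load aborted; invalid rows:\n  ",
         paste(errors, collapse = "\n  "))
  if (eager) records <- lapply(records, load_study)
  records
}

#' Materialise a study record's volumes in memory
#'
#' @param rec a [study_record] whose `dce`/`t2w` entries may be file paths.
#' @param dt_seconds DCE acquisition interval used when assembling the series.
#' @return the record with `dce` as a [dynamic_series] and `t2w` as an
#'   [image_volume].
#' @export
load_study <- function(rec, dt_seconds = 60) {
  stopifnot(inherits(rec, "study_record"))
  if (!inherits(rec$dce, "dynamic_series")) {
    pre <- read_volume(rec$dce$pre, "dce_pre")
    post <- lapply(seq_along(rec$dce$post), function(i)
      read_volume(rec$dce$post[[i]], paste0("dce_post", i)))
    rec$dce <- dynamic_series(pre, post, dt_seconds = dt_seconds)
  }
  if (!inherits(rec$t2w, "image_volume"))
    rec$t2w <- read_volume(rec$t2w, "t2w")
  rec
}

#' Write a cohort manifest CSV
#'
#' @param tab data.frame with the manifest columns (paths relative to `path`'s
#'   directory or absolute).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map a voxel mask into another volume's grid
#'
#' Transfers a binary mask between two axis-aligned grids by physical
#' (world-coordinate) nearest-neighbour lookup: each destination voxel centre
#' is mapped through origins and spacings into the source grid. This is how
#' DCE-frame lesion masks are carried to the T2w frame without
#' re-segmentation.
#'
#' @param mask logical 3D array in the source grid.
#' @param src_spacing,src_origin geometry of the source grid.
#' @param dst_dim,dst_spacing,dst_origin geometry of the destination grid.
#' @param offset_mm optional extra physical offset (mm, slice/row/col) added
#'   to destination coordinates before lookup (inter-sequence shift).
#' @return logical array of dimension `dst_dim`.
#' @export
mask_to_frame <- function(mask, src_spacing, src_origin,
                          dst_dim, dst_spacing, dst_origin,
                          offset_mm = c(0, 0, 0)) {
  stopifnot(length(dim(mask)) == 3L)
  maps <- lapply(1:3, function(a) {
    world <- dst_origin[a] + (seq_len(dst_dim[a]) - 1) * dst_spacing[a] +
      offset_mm[a]
    idx <- round((world - src_origin[a]) / src_spacing[a]) + 1L
    idx[idx < 1L | idx > dim(mask)[a]] <- NA_integer_
    idx
  })
  out <- array(FALSE, dst_dim)
  ok1 <- !is.na(maps[[1]]); ok2 <- !is.na(maps[[2]]); ok3 <- !is.na(maps[[3]])
  if (any(ok1) && any(ok2) && any(ok3)) {
    sub <- mask[maps[[1]][ok1], maps[[2]][ok2], maps[[3]][ok3], drop = FALSE]
    out[which(ok1), which(ok2), which(ok3)] <- sub
  }
  out
}
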