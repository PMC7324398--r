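# Multi-depth pooled deep feature extraction.
#
# A frozen 19-layer VGG-architecture convolutional network (16 conv layers in
# five blocks of 64/128/256/512/512 channels, 3x3 kernels, ReLU, 2x2
# max-pooling after each block) is run forward on a three-channel ROI. The
# activation map of each of the five max-pooling layers is average-pooled
# over its spatial dimensions and L2-normalised, and the five pooled vectors
# are concatenated in network order into the 1,472-element descriptor
# (64 + 128 + 256 + 512 + 512). Because pooling collapses the spatial axes,
# inputs of any size >= 32 px per side are accepted — no resizing.
#
# The forward pass is implemented with im2col + BLAS matrix multiplication;
# weights are never trained (frozen backbone). The random-weight mode is
# seed-deterministic and is what the test-suite uses; externally supplied
# pretrained weights can be loaded from an RDS file.

.vgg19_cfg <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L, 256L),
                   c(512L, 512L, 512L, 512L), c(512L, 512L, 512L, 512L))

#' Feature-block sizes of the backbone
#'
#' Channel counts of the five max-pooling layers, in network order; their sum
#' is the descriptor length 1,472.
#'
#' @return integer vector (64, 128, 256, 512, 512).
#' @export
feature_block_sizes <- function() vapply(.vgg19_cfg, function(b)
  b[length(b)], integer(1))

#' Load the frozen convolutional backbone
#'
#' Builds the 19-layer VGG-architecture network exposing the five max-pooling
#' activation maps. `weights = "random"` draws seed-deterministic
#' He-initialised weights, needs no download, and is what all structural
#' contracts are tested with; a path to an RDS file containing a compatible
#' weight list (e.g. converted pretrained weights) may be given instead.
#'
#' @param weights `"random"` or a path to an RDS weight file.
#' @param seed integer seed for the random-weight mode.
#' @return A `vgg_backbone` object (list of per-layer weight matrices).
#' @export
load_backbone <- function(weights = "random", seed = 1L) {
  if (identical(weights, "random")) {
    rs <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(rs)) assign(".Random.seed", rs,
                                     envir = globalenv()))
    set.seed(seed)
    layers <- list()
    cin <- 3L
    for (b in seq_along(.vgg19_cfg)) {
      for (cout in .vgg19_cfg[[b]]) {
        w <- matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                    9L * cin, cout)
        layers[[length(layers) + 1L]] <-
          list(w = w, b = numeric(cout), block = b)
        cin <- cout
      }
    }
    structure(list(layers = layers, source = sprintf("random(seed=%d)", seed),
                   norm_mean = c(0.485, 0.456, 0.406),
                   norm_sd = c(0.229, 0.224, 0.225)),
              class = "vgg_backbone")
  } else {
    if (!file.exists(weights))
      stop("backbone weight file not found: ", weights,
           "\n  (use weights = \"random\" for a download-free backbone)")
    bb <- readRDS(weights)
    if (!inherits(bb, "vgg_backbone"))
      stop("'", weights, "' does not contain a vgg_backbone object")
    bb
  }
}

#' @export
print.vgg_backbone <- function(x, ...) {
  cat(sprintf("<vgg_backbone> 16 conv layers, 5 pooling blocks (%s), %s\n",
              paste(feature_block_sizes(), collapse = "/"), x$source))
  invisible(x)
}

# 3x3 same-padding convolution via im2col. x: H x W x Cin array. Column
# order of the patch matrix is (offset-major, channel within offset),
# matching the weight layout used in load_backbone.
.conv3x3 <- function(x, w, bias) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cin <- dim(x)[3]
  pad <- array(0, c(h + 2L, wd + 2L, cin))
  pad[2:(h + 1), 2:(wd + 1), ] <- x
  cols <- matrix(0, h * wd, 9L * cin)
  k <- 0L
  for (di in 0:2) for (dj in 0:2) {
    blk <- pad[di + seq_len(h), dj + seq_len(wd), , drop = FALSE]
    cols[, k * cin + seq_len(cin)] <- blk
    k <- k + 1L
  }
  y <- cols %*% w
  if (any(bias != 0)) y <- sweep(y, 2, bias, "+")
  array(y, c(h, wd, ncol(w)))
}

# 2x2 stride-2 max-pooling (floor semantics on odd sizes).
.maxpool2 <- function(x) {
  h <- dim(x)[1] %/% 2L; w <- dim(x)[2] %/% 2L
  i <- seq_len(h) * 2L; j <- seq_len(w) * 2L
  pmax(x[i - 1L, j - 1L, , drop = FALSE], x[i - 1L, j, , drop = FALSE],
       x[i, j - 1L, , drop = FALSE], x[i, j, , drop = FALSE])
}

#' Extract the 1,472-element pooled descriptor from one ROI
#'
#' Runs the frozen backbone forward and, at each of the five max-pooling
#' layers, averages the activation map over its spatial dimensions and
#' divides the resulting channel vector by its Euclidean norm (identically
#' zero blocks are left at zero). The five vectors are concatenated in
#' network order.
#'
#' Inputs smaller than 32 px per side are zero-padded symmetrically to 32 so
#' that the five 2x halvings leave at least one spatial cell; images are
#' never resized. Each channel is min-max rescaled to [0, 1] and then
#' standardised with the backbone's channel normalisation constants.
#'
#' @param roi H x W x 3 array (a `fusion_roi`, or a grayscale ROI passed
#'   through [gray_to_rgb()]), or a 2D matrix which is channel-tripled.
#' @param backbone a `vgg_backbone` from [load_backbone()].
#' @return numeric vector of length 1,472 with a `blocks` attribute giving
#'   the five block sizes.
#' @export
extract_features <- function(roi, backbone) {
  stopifnot(inherits(backbone, "vgg_backbone"))
  if (is.matrix(roi)) roi <- gray_to_rgb(roi)
  roi <- unclass(roi)
  if (length(dim(roi)) != 3L || dim(roi)[3] != 3L)
    stop("ROI must be H x W x 3")
  if (!all(is.finite(roi))) stop("ROI contains non-finite values")
  h <- dim(roi)[1]; w <- dim(roi)[2]
  # per-channel min-max then channel standardisation
  x <- array(0, dim(roi))
  for (ch in 1:3)
    x[, , ch] <- (rescale01(roi[, , ch]) - backbone$norm_mean[ch]) /
      backbone$norm_sd[ch]
  # symmetric zero-padding to >= 32 per side
  th <- max(h, 32L); tw <- max(w, 32L)
  if (th > h || tw > w) {
    pad <- array(0, c(th, tw, 3L))
    r0 <- (th - h) %/% 2L; c0 <- (tw - w) %/% 2L
    pad[r0 + seq_len(h), c0 + seq_len(w), ] <- x
    x <- pad
  }
  feats <- numeric(0)
  li <- 0L
  for (b in seq_along(.vgg19_cfg)) {
    for (k in seq_along(.vgg19_cfg[[b]])) {
      li <- li + 1L
      layer <- backbone$layers[[li]]
      x <- .conv3x3(x, layer$w, layer$b)
      x[x < 0] <- 0
    }
    x <- .maxpool2(x)
    if (!all(is.finite(x))) stop("non-finite activations in block ", b)
    v <- apply(x, 3, mean)
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    feats <- c(feats, v)
  }
  structure(feats, blocks = feature_block_sizes())
}

#' Triple a grayscale ROI across the colour channels
#'
#' @param px 2D matrix (grayscale ROI).
#' @return H x W x 3 array with identical channels.
#' @export
gray_to_rgb <- function(px) {
  stopifnot(is.matrix(px))
  array(rep(px, 3L), c(dim(px), 3L))
}

#' Extract features for a whole cohort
#'
#' @param rois named list (by lesion id) of ROI inputs: 2D matrices for the
#'   grayscale single-sequence schemes, `fusion_roi` arrays for image fusion.
#' @param backbone a `vgg_backbone`.
#' @param scheme tag recorded with the output (`dce`, `t2w`, `image_fusion`).
#' @return numeric matrix, one row per lesion (rownames = lesion ids),
#'   columns `f0001`..`f1472`. Per-lesion failures are collected and
#'   re-raised after the full pass.
#' @export
featurize_cohort <- function(rois, backbone, scheme = "dce") {
  stopifnot(length(rois) > 0, !is.null(names(rois)))
  out <- matrix(NA_real_, length(rois), sum(feature_block_sizes()),
                dimnames = list(names(rois),
                                sprintf("f%04d",
                                        seq_len(sum(feature_block_sizes())))))
  failures <- character(0)
  for (i in seq_along(rois)) {
    fv <- tryCatch(extract_features(rois[[i]], backbone),
                   error = function(e) e)
    if (inherits(fv, "error"))
      failures <- c(failures, sprintf("%s: %s", names(rois)[i],
                                      conditionMessage(fv)))
    else out[i, ] <- fv
  }
  if (length(failures))
    stop("feature extraction failed for ", length(failures), " lesion(s) [",
         scheme, "]:\n  ", paste(failures, collapse = "\n  "))
  attr(out, "scheme") <- scheme
  out
}
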