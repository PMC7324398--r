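# Inter-sequence rigid registration (translation + rotation only).
#
# The T2w centre slice, already resampled to the DCE in-plane resolution, is
# registered to the corresponding DCE slice by maximising histogram-based
# mutual information over (tx, ty, theta) with a multi-level grid search
# followed by Nelder-Mead refinement. No scaling or shearing: altering lesion
# geometry is undesirable for a diagnostic pipeline.

#' Rigid 2D transform
#'
#' @param tx_mm,ty_mm translation (row, col direction) in mm.
#' @param theta_deg rotation in degrees, counter-clockwise about the image
#'   centre.
#' @param metric_value similarity value at the optimum (if any).
#' @return A `rigid_transform2d` object.
#' @export
rigid_transform2d <- function(tx_mm = 0, ty_mm = 0, theta_deg = 0,
                              metric_value = NA_real_) {
  structure(list(tx_mm = tx_mm, ty_mm = ty_mm, theta_deg = theta_deg,
                 metric_value = metric_value),
            class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("<rigid_transform2d> t = (%.2f, %.2f) mm, theta = %.2f deg\n",
              x$tx_mm, x$ty_mm, x$theta_deg))
  invisible(x)
}

#' Invert a rigid transform
#'
#' @param t a `rigid_transform2d`.
#' @return its inverse; composing the two is the identity.
#' @export
invert_transform <- function(t) {
  th <- -t$theta_deg * pi / 180
  # inverse of x' = R x + t is x = R^T x' - R^T t
  rigid_transform2d(-(cos(th) * t$tx_mm - sin(th) * t$ty_mm),
                    -(sin(th) * t$tx_mm + cos(th) * t$ty_mm),
                    -t$theta_deg)
}

# Bicubic sampling of `px` at fractional (row, col) 0-based coordinates,
# zero-filled outside the domain. Vectorised 16-neighbour gather.
.sample_bicubic <- function(px, rows, cols) {
  n <- nrow(px); m <- ncol(px)
  out <- numeric(length(rows))
  inside <- rows > -0.5 & rows < n - 0.5 & cols > -0.5 & cols < m - 0.5
  if (!any(inside)) return(out)
  r <- rows[inside]; c <- cols[inside]
  br <- floor(r); bc <- floor(c)
  acc <- numeric(length(r)); wsum <- numeric(length(r))
  for (dr in -1:2) {
    ir <- br + dr
    wr <- .cubic_kernel(r - ir)
    ir <- pmin(pmax(ir, 0), n - 1)
    for (dc in -1:2) {
      ic <- bc + dc
      wc <- .cubic_kernel(c - ic)
      ic <- pmin(pmax(ic, 0), m - 1)
      w <- wr * wc
      acc <- acc + w * px[cbind(ir + 1, ic + 1)]
      wsum <- wsum + w
    }
  }
  out[inside] <- acc / wsum
  out
}

#' Apply a rigid transform to a 2D image
#'
#' Resamples the image under the rigid map (rotation about the image centre,
#' then translation) with bicubic interpolation; pixels mapping outside the
#' source domain are zero-filled.
#'
#' @param img a `roi2d`, or a matrix with `spacing` given.
#' @param t a `rigid_transform2d`.
#' @param spacing pixel spacing when `img` is a bare matrix.
#' @return A `roi2d` on the same grid.
#' @export
apply_transform <- function(img, t, spacing = NULL) {
  .transform_with_mask(img, t, spacing)$image
}

# As apply_transform, but also reports which output pixels had in-domain
# source support (the overlap region a registration metric should use).
.transform_with_mask <- function(img, t, spacing = NULL) {
  if (inherits(img, "roi2d")) {
    px <- img$pixels; spacing <- img$pixel_spacing_mm; tag <- img$source_tag
  } else {
    px <- img; tag <- ""
    if (is.null(spacing)) stop("spacing required for a bare matrix")
  }
  n <- nrow(px); m <- ncol(px)
  ctr <- c((n - 1) / 2, (m - 1) / 2)
  th <- t$theta_deg * pi / 180
  grid_r <- (slice.index(px, 1) - 1 - ctr[1]) * spacing[1]
  grid_c <- (slice.index(px, 2) - 1 - ctr[2]) * spacing[2]
  # inverse map: output position -> source position
  src_r <- cos(th) * (grid_r - t$tx_mm) + sin(th) * (grid_c - t$ty_mm)
  src_c <- -sin(th) * (grid_r - t$tx_mm) + cos(th) * (grid_c - t$ty_mm)
  rows <- src_r / spacing[1] + ctr[1]
  cols <- src_c / spacing[2] + ctr[2]
  vals <- .sample_bicubic(px, rows, cols)
  inside <- rows > -0.5 & rows < n - 0.5 & cols > -0.5 & cols < m - 0.5
  list(image = roi2d(matrix(vals, n, m), spacing, tag),
       inside = matrix(inside, n, m))
}

#' Histogram-based mutual information of two images
#'
#' Joint intensities are accumulated with partial-volume (bilinear)
#' weighting into the histogram, so the estimate varies smoothly as one
#' image is transformed — hard-binned histograms produce a jagged metric
#' surface that derails continuous optimisation.
#'
#' @param a,b numeric matrices (or vectors) of equal length.
#' @param bins joint-histogram bins per axis (default 32).
#' @return mutual information in nats.
#' @export
mutual_information <- function(a, b, bins = 32L) {
  stopifnot(length(a) == length(b))
  a <- as.numeric(a); b <- as.numeric(b)
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2])
    stop("no gradient information: constant image")
  # continuous bin coordinates in [0, bins-1]
  ua <- (a - ra[1]) / (ra[2] - ra[1]) * (bins - 1L)
  ub <- (b - rb[1]) / (rb[2] - rb[1]) * (bins - 1L)
  fa <- floor(ua); fb <- floor(ub)
  wa <- ua - fa; wb <- ub - fb
  ia0 <- pmin(fa, bins - 1L); ia1 <- pmin(fa + 1, bins - 1L)
  ib0 <- pmin(fb, bins - 1L); ib1 <- pmin(fb + 1, bins - 1L)
  idx <- c(ia0 * bins + ib0, ia0 * bins + ib1,
           ia1 * bins + ib0, ia1 * bins + ib1) + 1
  w <- c((1 - wa) * (1 - wb), (1 - wa) * wb, wa * (1 - wb), wa * wb)
  joint <- numeric(bins * bins)
  acc <- rowsum(w, idx)
  joint[as.integer(rownames(acc))] <- acc[, 1]
  pm <- matrix(joint / sum(joint), bins, bins, byrow = TRUE)
  pa <- rowSums(pm); pb <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / (pa[row(pm)[nz]] * pb[col(pm)[nz]])))
}

#' Rigid multimodal registration of two 2D images
#'
#' Finds the translation + rotation maximising the mutual information of the
#' transformed moving image with the fixed image: a multi-level grid search
#' over (+-10 mm, +-10 deg) followed by Nelder-Mead refinement. Deterministic
#' given the inputs. The histogram metric makes the method multimodal —
#' invariant to contrast direction.
#'
#' @param moving,fixed `roi2d` images on matching grids (resample first).
#' @param search_mm,search_deg half-widths of the coarse search window.
#' @param bins histogram bins for the metric.
#' @param penalty weight of a quadratic regulariser on (tx, ty, theta) that
#'   breaks metric ties toward the identity. On scenes with rotational
#'   near-symmetry (a single round lesion) the rotation is otherwise
#'   unidentified and the optimiser would return an arbitrary angle; the
#'   penalty is far too small to bias a genuinely informative optimum.
#' @return A `rigid_transform2d` such that `apply_transform(moving, t)`
#'   aligns with `fixed`; `metric_value` holds the attained MI.
#' @export
register_rigid <- function(moving, fixed, search_mm = 10, search_deg = 10,
                           bins = 32L, penalty = 1e-4) {
  stopifnot(inherits(moving, "roi2d"), inherits(fixed, "roi2d"))
  if (!identical(dim(moving$pixels), dim(fixed$pixels)))
    stop("register_rigid requires images on matching grids")
  if (diff(range(moving$pixels)) == 0 || diff(range(fixed$pixels)) == 0)
    stop("no gradient information: constant image")
  sp <- moving$pixel_spacing_mm
  # the metric is evaluated on a regular pixel subsample for large slices:
  # the MI estimate saturates well below full density and the search cost
  # drops with the pixel count
  px <- moving$pixels
  n <- nrow(px); m <- ncol(px)
  stride <- if (length(px) > 9000) 2L else 1L
  sub_r <- seq(1, n, by = stride)
  sub_c <- seq(1, m, by = stride)
  fixed_sub <- as.numeric(fixed$pixels[sub_r, sub_c])
  ctr <- c((n - 1) / 2, (m - 1) / 2)
  grid_r <- outer((sub_r - 1 - ctr[1]) * sp[1], rep(1, length(sub_c)))
  grid_c <- outer(rep(1, length(sub_r)), (sub_c - 1 - ctr[2]) * sp[2])
  score <- function(par) {
    th <- par[3] * pi / 180
    src_r <- cos(th) * (grid_r - par[1]) + sin(th) * (grid_c - par[2])
    src_c <- -sin(th) * (grid_r - par[1]) + cos(th) * (grid_c - par[2])
    rows <- src_r / sp[1] + ctr[1]
    cols <- src_c / sp[2] + ctr[2]
    ok <- rows > -0.5 & rows < n - 0.5 & cols > -0.5 & cols < m - 0.5
    # overlap region only: border fill must not drive the metric
    if (sum(ok) < 0.25 * length(ok)) return(-Inf)
    vals <- .sample_bicubic(px, rows[ok], cols[ok])
    mi <- tryCatch(mutual_information(vals, fixed_sub[ok], bins = bins),
                   error = function(e) -Inf)
    mi - penalty * sum(par^2)
  }
  # level 1: coarse grid; keep several candidate basins, since a smooth
  # metric can rank a wrong cell first at coarse resolution
  g1 <- expand.grid(tx = seq(-search_mm, search_mm, length.out = 7),
                    ty = seq(-search_mm, search_mm, length.out = 7),
                    th = seq(-search_deg, search_deg, length.out = 7))
  s1 <- apply(g1, 1, score)
  seeds <- utils::head(order(s1, decreasing = TRUE), 3L)
  # level 2: refine each candidate basin, keep the overall best
  step <- c(search_mm, search_mm, search_deg) / 6
  best <- NULL; best_score <- -Inf
  for (i in seeds) {
    cand <- as.numeric(g1[i, ])
    g2 <- expand.grid(tx = cand[1] + seq(-2, 2, 1) * step[1],
                      ty = cand[2] + seq(-2, 2, 1) * step[2],
                      th = cand[3] + seq(-2, 2, 1) * step[3])
    s2 <- apply(g2, 1, score)
    if (max(s2) > best_score) {
      best_score <- max(s2)
      best <- as.numeric(g2[which.max(s2), ])
    }
  }
  # level 3: local simplex refinement
  opt <- stats::optim(best, function(p) -score(p), method = "Nelder-Mead",
                      control = list(maxit = 150, reltol = 1e-7,
                                     parscale = c(1, 1, 1)))
  rigid_transform2d(opt$par[1], opt$par[2], opt$par[3],
                    metric_value = -opt$value)
}
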