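# Seeded fuzzy C-means lesion segmentation.
#
# The lesion is segmented on the second post-contrast subtraction volume from
# a single user-supplied seed point: voxel intensities inside a physical
# search box around the seed are clustered with fuzzy C-means, the
# highest-intensity cluster is taken as lesion, thresholded at membership
# 0.5, and restricted to the 26-connected component containing the seed.

#' Fuzzy C-means parameters
#'
#' @param n_clusters number of intensity clusters (>= 2).
#' @param m fuzziness exponent (> 1).
#' @param tol convergence tolerance on the maximum membership change
#'   between iterations (scale-invariant).
#' @param max_iter iteration cap; non-convergence is an error.
#' @param search_box_mm half-width (mm) of the cuboid search region centred
#'   on the seed point.
#' @return An `fcm_params` list.
#' @export
fcm_params <- function(n_clusters = 2L, m = 2.0, tol = 1e-5, max_iter = 200L,
                       search_box_mm = 30) {
  stopifnot(n_clusters >= 2, m > 1, tol > 0, max_iter >= 1, search_box_mm > 0)
  structure(list(n_clusters = as.integer(n_clusters), m = m, tol = tol,
                 max_iter = as.integer(max_iter),
                 search_box_mm = search_box_mm),
            class = "fcm_params")
}

#' Fuzzy C-means clustering of scalar intensities
#'
#' Minimises sum_ik u_ik^m (x_i - c_k)^2 subject to sum_k u_ik = 1 by
#' alternating membership and centroid updates. Initialisation is
#' deterministic and equivariant under affine intensity rescaling: the lower
#' K-1 centroids start at evenly spaced intensity quantiles (probabilities
#' (2k-1)/2K) and the top centroid starts at the intensity maximum, so a
#' bright structure occupying only a small voxel fraction (far beyond any
#' bulk quantile) is still captured by the highest cluster. The objective
#' value is tracked per iteration and verified to be non-increasing.
#'
#' @param x numeric vector of intensities.
#' @param params an [fcm_params] object.
#' @return list with `membership` (n x K matrix, rows summing to 1),
#'   `centers` (ascending at initialisation order), `objective` (per-iteration
#'   values), `iterations`.
#' @export
fcm_cluster <- function(x, params = fcm_params()) {
  stopifnot(is.numeric(x), length(x) >= params$n_clusters)
  K <- params$n_clusters
  expo <- 1 / (params$m - 1)
  centers <- as.numeric(stats::quantile(x, probs = (2 * seq_len(K) - 1) /
                                          (2 * K), names = FALSE))
  centers[K] <- max(x)
  # coincident initial centroids (e.g. constant regions) get nudged apart
  if (any(duplicated(centers)))
    centers <- centers + (seq_len(K) - (K + 1) / 2) * 1e-8 *
      max(diff(range(x)), 1)
  n <- length(x)
  u <- matrix(0, n, K)
  obj <- numeric(0)
  for (it in seq_len(params$max_iter)) {
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    d2 <- pmax(d2, .Machine$double.xmin)
    w <- d2^(-expo)
    u_new <- w / rowSums(w)
    um <- u_new^params$m
    obj <- c(obj, sum(um * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    centers_new <- colSums(um * x) / colSums(um)
    if (delta < params$tol) {
      centers <- centers_new
      break
    }
    centers <- centers_new
    if (it == params$max_iter)
      stop("fuzzy C-means did not converge in ", params$max_iter,
           " iterations")
  }
  list(membership = u, centers = centers, objective = obj, iterations = it)
}

# 26-connected component of `mask` containing `seed_idx` (1-based c(i,j,k)).
# Grown by iterated vectorised dilation restricted to the mask.
.connected_component_26 <- function(mask, seed_idx) {
  d <- dim(mask)
  comp <- array(FALSE, d)
  comp[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  shifts <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  shifts <- shifts[!(shifts$di == 0 & shifts$dj == 0 & shifts$dk == 0), ]
  repeat {
    grown <- comp
    for (s in seq_len(nrow(shifts))) {
      di <- shifts$di[s]; dj <- shifts$dj[s]; dk <- shifts$dk[s]
      src_i <- max(1, 1 - di):min(d[1], d[1] - di)
      src_j <- max(1, 1 - dj):min(d[2], d[2] - dj)
      src_k <- max(1, 1 - dk):min(d[3], d[3] - dk)
      grown[src_i + di, src_j + dj, src_k + dk] <-
        grown[src_i + di, src_j + dj, src_k + dk] |
        comp[src_i, src_j, src_k]
    }
    grown <- grown & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

#' Count 26-connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @return integer component count.
#' @export
count_components_26 <- function(mask) {
  n <- 0L
  remaining <- mask
  while (any(remaining)) {
    seed <- which(remaining, arr.ind = TRUE)[1, ]
    comp <- .connected_component_26(remaining, seed)
    remaining <- remaining & !comp
    n <- n + 1L
  }
  n
}

#' Seeded fuzzy C-means lesion segmentation
#'
#' Runs fuzzy C-means on the intensities of the enhancement (second
#' post-contrast subtraction) volume within a physical search box around the
#' seed, labels the highest-centroid cluster as lesion, thresholds its
#' membership at 0.5, and keeps the 26-connected component containing the
#' seed.
#'
#' When a lesion is small relative to the search box, a low cluster count
#' can minimise the objective by splitting the background instead of
#' isolating the lesion, which yields an implausibly large seeded component
#' with weak intensity separation, or a lesion-plus-noise component fused by
#' connectivity percolation. A candidate component is therefore accepted
#' only if it is decisively brighter than the remaining box voxels (mean
#' difference at least 3 remainder-SDs; percolated or split-noise components
#' sit well below that) and additionally, when it exceeds
#' `max_box_fraction` of the box, shows the stronger contrast (> 4
#' remainder-SDs) only a genuinely large lesion produces. Otherwise the
#' cluster count is escalated (up to `max_clusters`). For very small lesions
#' even many clusters cannot hold a centroid against the background's sheer
#' voxel mass, so on failure the search box is halved (down to a 5 mm
#' half-width) and the escalation retried; an error is raised only when
#' every scale fails.
#'
#' @param enhancement_volume an [image_volume]; by convention the
#'   post2 - pre subtraction volume (see [subtraction_volume()]).
#' @param seed integer length-3, 0-based (slice, row, col) voxel index.
#' @param params an [fcm_params] object.
#' @param max_clusters escalation limit for the cluster count.
#' @param max_box_fraction largest plausible seeded-component fraction of
#'   the search box.
#' @return A `lesion_mask`: list with `mask` (logical 3D array on the input
#'   grid), `seed_point` (0-based), `spacing`, `component_count` (always 1),
#'   `n_clusters_used`, and the FCM `objective` trace.
#' @export
fcm_segment <- function(enhancement_volume, seed, params = fcm_params(),
                        max_clusters = 6L, max_box_fraction = 0.25) {
  stopifnot(inherits(enhancement_volume, "image_volume"))
  vox <- enhancement_volume$voxels
  d <- dim(vox)
  seed1 <- as.integer(seed) + 1L
  if (any(seed1 < 1L) || any(seed1 > d))
    stop("seed point (", paste(seed, collapse = ","),
         ") outside the voxel grid")

  box_mm <- params$search_box_mm
  last_err <- "seed outside segmentation"
  while (box_mm >= 5) {
    half <- pmax(1L, as.integer(round(box_mm /
                                        enhancement_volume$spacing)))
    lo <- pmax(seed1 - half, 1L)
    hi <- pmin(seed1 + half, d)
    box <- vox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    seed_in_box <- seed1 - lo + 1L

    for (k in params$n_clusters:max_clusters) {
      pk <- params; pk$n_clusters <- k
      fit <- fcm_cluster(as.numeric(box), pk)
      if (any(diff(fit$objective) > 1e-8 * max(fit$objective[1], 1)))
        stop("FCM objective increased between iterations")
      lesion_k <- which.max(fit$centers)
      in_mask <- array(fit$membership[, lesion_k] > 0.5, dim(box))
      if (!in_mask[seed_in_box[1], seed_in_box[2], seed_in_box[3]]) {
        last_err <- "seed outside segmentation"
        next
      }
      cand <- .connected_component_26(in_mask, seed_in_box)
      frac <- sum(cand) / length(box)
      sep <- if (frac < 1) {
        rest <- box[!cand]
        contrast <- mean(box[cand]) - mean(rest)
        if (stats::sd(rest) > 0) contrast / stats::sd(rest)
        else sign(contrast) * Inf
      } else -Inf
      if (sep >= 3 && (frac <= max_box_fraction || sep > 4)) {
        mask <- array(FALSE, d)
        mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- cand
        return(structure(list(mask = mask,
                              seed_point = as.integer(seed),
                              spacing = enhancement_volume$spacing,
                              component_count = 1L, n_clusters_used = k,
                              search_box_mm_used = box_mm,
                              objective = fit$objective),
                         class = "lesion_mask"))
      }
      last_err <- paste0("seeded component covers ", round(100 * frac),
                         "% of the search box without decisive contrast")
    }
    box_mm <- box_mm / 2
  }
  stop(last_err)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d voxels, effective diameter %.1f mm\n",
              sum(x$mask), effective_diameter(x)))
  invisible(x)
}

#' Effective lesion diameter
#'
#' Diameter of the sphere with the same volume as the mask:
#' 2 * (3V / 4pi)^(1/3) with V = voxel count x voxel volume.
#'
#' @param mask a `lesion_mask`, or a logical/0-1 3D array.
#' @param spacing voxel spacing in mm; taken from the mask object if absent.
#' @return effective diameter in mm.
#' @export
effective_diameter <- function(mask, spacing = NULL) {
  if (inherits(mask, "lesion_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    mask <- mask$mask
  }
  if (is.null(spacing)) stop("spacing required for a bare mask array")
  n <- sum(mask != 0)
  if (n == 0L) stop("empty mask has no effective diameter")
  v <- n * prod(spacing)
  2 * (3 * v / (4 * pi))^(1 / 3)
}

#' Dice overlap of two masks
#'
#' @param a,b logical arrays of equal dimension.
#' @return Dice coefficient 2|A&B| / (|A|+|B|).
#' @export
dice_overlap <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
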