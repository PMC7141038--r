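#' Otsu threshold of an intensity array
#'
#' Computes the threshold that maximises the between-class intensity variance
#' over a 256-bin histogram of the whole stack (all planes pooled). The
#' returned value lies on the intensity scale of the input; voxels with
#' intensity greater than or equal to it are considered stained.
#'
#' @param x numeric array or [image_stack()].
#' @param n_bins number of histogram bins.
#' @return A single threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.vector(unclass(x))
  rng <- range(v)
  if (diff(rng) == 0) {
    abort("degenerate histogram: image is constant, cannot apply Otsu.")
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(
    pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins),
    nbins = n_bins
  )
  w <- h / sum(h)
  mids <- (head(breaks, -1) + breaks[-1]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  # threshold = upper edge of the background class: ">= threshold" is stained
  breaks[k + 1L]
}

#' Segment the stained foreground
#'
#' Produces the f-actin-positive foreground mask that feeds the migration
#' classification: voxels whose (optionally pre-smoothed) intensity is greater
#' than or equal to a threshold, chosen either automatically by Otsu's method
#' on the full stack or supplied as a fixed value.
#'
#' @param stack an [image_stack()].
#' @param method `"otsu"` (default, parameter-free) or `"fixed"`.
#' @param fixed_threshold intensity threshold, required when
#'   `method = "fixed"`.
#' @param smooth_sigma optional dual-scale denoising (voxels, default 0 =
#'   none): the threshold is additionally applied to a Gaussian-smoothed copy
#'   of the stack and the two masks are united. Smoothing stabilises extended
#'   surfaces (the spheroid body) against noise-induced dents, while the raw
#'   mask preserves thin sprouts and small cells that smoothing would erode.
#' @param min_object_size drop connected foreground objects smaller than this
#'   many voxels (default 0 = keep all) before the smoothed mask is united;
#'   removes threshold speckle from noisy images.
#' @param fill_holes fill enclosed background cavities of the final mask
#'   (background components not connected to the image border). Keeps
#'   noise-induced interior holes from distorting the distance transform.
#' @param connectivity connectivity used for the object-size filter and hole
#'   filling; default 26 (3D) / 8 (2D).
#' @return A `foreground_mask`: logical array with attributes
#'   `threshold_used`, `method` and `spacing`. With all cleanup options at
#'   their defaults, every masked voxel has intensity `>= threshold_used`;
#'   `fill_holes` and `smooth_sigma` may add voxels below the threshold.
#' @examples
#' img <- image_stack(matrix(c(0, 10, 200, 255), 2, 2))
#' m <- segment_foreground(img, method = "fixed", fixed_threshold = 128)
#' sum(m)
#' @export
segment_foreground <- function(stack, method = c("otsu", "fixed"),
                               fixed_threshold = NULL, smooth_sigma = 0,
                               min_object_size = 0, fill_holes = FALSE,
                               connectivity = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  arr <- unclass(stack)
  thr <- switch(method,
    otsu = otsu_threshold(arr),
    fixed = {
      if (is.null(fixed_threshold)) {
        abort("`fixed_threshold` is required when method = \"fixed\".")
      }
      as.numeric(fixed_threshold)
    }
  )
  mask <- arr >= thr
  connectivity <- check_connectivity(connectivity, dim(mask))
  if (min_object_size > 0) {
    mask <- drop_small_objects(mask, min_object_size, connectivity)
  }
  if (smooth_sigma > 0) {
    mask <- mask | (gaussian_smooth(arr, smooth_sigma) >= thr)
  }
  if (fill_holes) mask <- fill_mask_holes(mask)
  if (!any(mask)) {
    abort("no foreground: no voxel reaches threshold ", signif(thr, 6), ".")
  }
  structure(mask,
    threshold_used = thr, method = method,
    spacing = stack_spacing(stack),
    class = c("foreground_mask", "array")
  )
}

# remove connected foreground objects below `min_size` voxels
drop_small_objects <- function(mask, min_size, connectivity) {
  d <- dim(mask)
  lab <- .cc_label(mask, d, connectivity)
  if (max(lab) == 0L) {
    return(mask)
  }
  sizes <- tabulate(lab[lab > 0L])
  array(lab %in% which(sizes >= min_size), dim = d)
}

# fill background components that do not touch the image border; the
# complement is labeled with the minimal (face) connectivity, the standard
# dual of a 26/8-connected foreground
fill_mask_holes <- function(mask) {
  d <- dim(mask)
  bg <- .cc_label(!mask, d, if (d[3] > 1) 6L else 4L)
  if (max(bg) == 0L) {
    return(mask)
  }
  border <- unique(c(
    bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
    bg[, , 1], bg[, , d[3]]
  ))
  mask[bg > 0L & !(bg %in% border)] <- TRUE
  mask
}

#' @export
print.foreground_mask <- function(x, ...) {
  cat(sprintf(
    "<foreground_mask> %s, %d/%d voxels, threshold %.6g (%s)\n",
    paste(dim(x), collapse = "x"), sum(x), length(x),
    attr(x, "threshold_used"), attr(x, "method")
  ))
  invisible(x)
}

# coerce a plain logical array into a foreground_mask (used by tests and by
# callers that build masks directly)
as_foreground_mask <- function(mask, spacing = 1, threshold = NA_real_,
                               method = "fixed") {
  mask <- as_array3d(mask)
  storage.mode(mask) <- "logical"
  structure(mask,
    threshold_used = threshold, method = method,
    spacing = check_spacing(spacing),
    class = c("foreground_mask", "array")
  )
}

default_connectivity <- function(d) if (d[3] > 1) 26L else 8L

check_connectivity <- function(connectivity, d) {
  if (is.null(connectivity)) {
    return(default_connectivity(d))
  }
  connectivity <- as.integer(connectivity)
  if (d[3] > 1 && !connectivity %in% c(6L, 18L, 26L)) {
    abort("3D connectivity must be 6, 18 or 26.")
  }
  if (d[3] == 1 && !connectivity %in% c(4L, 8L)) {
    abort("2D connectivity must be 4 or 8.")
  }
  connectivity
}

#' Locate the spheroid center and core region
#'
#' Finds the microtissue center as the deepest interior point of the largest
#' connected foreground component: the voxel maximising the Euclidean
#' distance transform (computed with the physical voxel spacing), with ties
#' broken by the lowest column-major index. The maximal distance-transform
#' value is the estimated core radius, and the core region is the part of
#' that component lying strictly within this radius of the center.
#'
#' The distance-transform argmax is preferred over a centroid because
#' asymmetric sprouts pull a centroid off-center but cannot move the deepest
#' interior point of the core. When the mask contains several components
#' (detached single cells are expected), the largest one is taken as the
#' spheroid body and a message reports the component count.
#'
#' @param mask a `foreground_mask` from [segment_foreground()].
#' @param spacing physical voxel spacing; defaults to the spacing recorded on
#'   the mask.
#' @param connectivity neighbourhood connectivity (3D: 6/18/26, 2D: 4/8);
#'   default 26 in 3D, 8 in 2D.
#' @return A `core_estimate` list: `center` (1-based voxel coordinates),
#'   `core_radius_est` (physical length), `core_mask` (logical array),
#'   `component_mask` (the largest component), `n_components`, `spacing` and
#'   `connectivity`.
#' @export
estimate_core <- function(mask, spacing = NULL, connectivity = NULL) {
  stopifnot(inherits(mask, "foreground_mask"))
  if (!any(mask)) abort("empty mask.")
  d <- dim(mask)
  spacing <- check_spacing(spacing %||% attr(mask, "spacing") %||% 1)
  connectivity <- check_connectivity(connectivity, d)
  lab <- .cc_label(unclass(mask), d, connectivity)
  n_comp <- max(lab)
  if (n_comp > 1) {
    message(
      "foreground has ", n_comp,
      " connected components; using the largest as the spheroid body."
    )
  }
  comp <- lab == 1L
  dt <- .edt(comp, d, spacing)
  dmax <- max(dt)
  center_idx <- which(dt == dmax)[1] # lowest column-major index on ties
  center <- index_voxel(center_idx, d)
  dist2 <- dist2_from(d, center, spacing)
  # strictly inside the estimated radius; the 1e-6 guard absorbs the roundoff
  # of squaring the sqrt from the distance transform, so voxels exactly at
  # the radius stay outside the core
  core_mask <- comp & (dist2 < dmax^2 - 1e-6)
  core_mask[center_idx] <- TRUE # degenerate case: radius-0 tie
  structure(
    list(
      center = center, core_radius_est = dmax, core_mask = core_mask,
      component_mask = comp, n_components = n_comp,
      spacing = spacing, connectivity = connectivity
    ),
    class = "core_estimate"
  )
}

#' @export
print.core_estimate <- function(x, ...) {
  cat(sprintf(
    "<core_estimate> center (%s), radius %.4g, %d core voxels, %d component(s)\n",
    paste(x$center, collapse = ", "), x$core_radius_est,
    sum(x$core_mask), x$n_components
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# message-assembling wrappers: pieces are pasted, then signalled via rlang
abort <- function(...) rlang::abort(paste0(...))
warn <- function(...) rlang::warn(paste0(...))
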