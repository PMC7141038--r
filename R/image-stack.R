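#' Image stacks
#'
#' An `image_stack` is the package's container for single-channel fluorescence
#' images: a numeric array of intensities with per-axis physical voxel spacing.
#' Arrays are stored in R's native column-major order with dimensions
#' `(row, column, plane)`; a 2D image is a stack with a single plane. Voxel
#' indices are 1-based and all reported distances are physical, i.e. index
#' differences multiplied by `spacing` (so with the default unit spacing,
#' distances are in pixels).
#'
#' @param data numeric matrix (2D image) or 3D array of non-negative, finite
#'   intensities.
#' @param spacing physical size of one voxel along each axis
#'   (row, column, plane); a scalar is recycled. Must be positive.
#' @param name identifier carried through to results.
#' @return An `image_stack`: the intensity array with `spacing` and `name`
#'   attributes.
#' @examples
#' img <- image_stack(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
image_stack <- function(data, spacing = 1, name = "image") {
  if (!is.numeric(data) && !is.logical(data)) {
    abort("`data` must be a numeric array.")
  }
  data <- as_array3d(data)
  if (anyNA(data) || any(!is.finite(data))) {
    abort("intensities must be finite and non-missing.")
  }
  if (any(data < 0)) {
    abort("intensities must be non-negative.")
  }
  spacing <- check_spacing(spacing)
  structure(data,
    spacing = spacing, name = as.character(name)[1],
    class = c("image_stack", "array")
  )
}

# Promote a matrix to a single-plane 3D array; pass 3D arrays through.
as_array3d <- function(x) {
  d <- dim(x)
  if (is.null(d)) abort("`data` must have dimensions (a matrix or 3D array).")
  if (length(d) == 2) {
    dim(x) <- c(d, 1L)
  } else if (length(d) != 3) {
    abort("`data` must be a 2D matrix or 3D array, got ", length(d), " dims.")
  }
  storage.mode(x) <- "double"
  x
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) == 2) spacing <- c(spacing, 1)
  if (length(spacing) != 3 || anyNA(spacing) || any(spacing <= 0)) {
    abort("`spacing` must be 1-3 positive values (row, column, plane).")
  }
  spacing
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_stack> '%s' %d x %d x %d, spacing (%s), range [%.4g, %.4g]\n",
    attr(x, "name"), d[1], d[2], d[3],
    paste(signif(attr(x, "spacing"), 4), collapse = ", "),
    min(x), max(x)
  ))
  invisible(x)
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @export
stack_spacing <- function(x) attr(x, "spacing")

#' Maximum-intensity projection
#'
#' Collapses a z-stack to a single 2D plane by taking the per-pixel maximum
#' across planes. Acquired z-stacks can be quantified either in full 3D or on
#' their projection (the `mode` argument of [quantify_stack()]).
#'
#' @param stack an [image_stack()].
#' @return A single-plane `image_stack` with the same in-plane spacing.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack)
  proj <- apply(unclass(stack), c(1, 2), max)
  image_stack(proj,
    spacing = c(stack_spacing(stack)[1:2], 1),
    name = paste0(attr(stack, "name"), "_mip")
  )
}

# Squared physical distance of every voxel from `center` (1-based voxel
# coordinates, length 3), as an array of dim `d`.
dist2_from <- function(d, center, spacing = c(1, 1, 1)) {
  dy2 <- ((seq_len(d[1]) - center[1]) * spacing[1])^2
  dx2 <- ((seq_len(d[2]) - center[2]) * spacing[2])^2
  dz2 <- ((seq_len(d[3]) - center[3]) * spacing[3])^2
  array(
    rep(dy2, times = d[2] * d[3]) +
      rep(rep(dx2, each = d[1]), times = d[3]) +
      rep(dz2, each = d[1] * d[2]),
    dim = d
  )
}

# linear index (1-based, column-major) of a voxel coordinate
voxel_index <- function(coord, d) {
  (coord[3] - 1) * d[1] * d[2] + (coord[2] - 1) * d[1] + coord[1]
}

# inverse of voxel_index
index_voxel <- function(i, d) {
  i0 <- i - 1
  c(
    i0 %% d[1],
    (i0 %/% d[1]) %% d[2],
    i0 %/% (d[1] * d[2])
  ) + 1
}

#' Separable Gaussian smoothing of an image stack
#'
#' Convolves the stack with an isotropic (in voxel units) Gaussian kernel,
#' applied separably along each axis and renormalised at the borders. Used for
#' the optional point-spread-function blur of the synthetic generator and for
#' pre-threshold denoising.
#'
#' @param x numeric array or [image_stack()].
#' @param sigma Gaussian standard deviation in voxels; `0` returns the input
#'   unchanged.
#' @return The smoothed array (same class and attributes as the input).
#' @export
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) {
    return(x)
  }
  a <- attributes(x)
  arr <- unclass(x)
  d <- dim(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  ones <- array(1, dim = d)
  for (axis in 1:3) {
    if (d[axis] > 1) {
      arr <- convolve_axis(arr, k, axis)
      ones <- convolve_axis(ones, k, axis)
    }
  }
  out <- arr / ones
  attributes(out) <- a
  out
}

# 1D convolution along one axis of a 3D array via shifted accumulation,
# zero-padded (caller renormalises with a ones-array convolution).
convolve_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a2 <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a2, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  r <- (length(k) - 1L) / 2L
  for (j in seq_along(k)) {
    off <- j - r - 1L # source row = target row + off
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    tgt <- which(keep)
    out[tgt, ] <- out[tgt, ] + k[j] * m[src[keep], , drop = FALSE]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}
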