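#' Classify foreground voxels into collective vs single-cell migration
#'
#' Implements the central readout of the outgrowth assay: stained voxels that
#' belong to the connected network originating from the spheroid center are
#' collective migration; stained voxels outside that network are single-cell
#' (mesenchymal-type) migration. The spheroid body itself — the part of the
#' network inside the estimated core radius — is labeled `core` and excluded
#' from both migrating classes.
#'
#' Optionally, single-cell objects smaller than `min_single_size` voxels are
#' suppressed (relabeled background) to reject residual segmentation speckle;
#' the default of 1 disables the filter, leaving noise control to
#' segmentation.
#'
#' @param mask a `foreground_mask` from [segment_foreground()].
#' @param core a `core_estimate` from [estimate_core()].
#' @param connectivity neighbourhood connectivity (3D: 6/18/26, 2D: 4/8);
#'   default 26 in 3D, 8 in 2D.
#' @param min_single_size minimum voxel count of a single-cell object;
#'   smaller isolated objects are discarded as background.
#' @return A `migration_labels` object: integer array coded 0 = background,
#'   1 = core, 2 = collective, 3 = single, with the connectivity, center and
#'   spacing as attributes.
#' @examples
#' m <- matrix(0, 7, 7)
#' m[3:5, 3:5] <- 1 # core block
#' m[4, 6] <- 1 # start of an arm
#' m[1, 1] <- 1 # isolated cell
#' # ... see vignette for the full pipeline on generated images
#' @export
classify_migration <- function(mask, core, connectivity = NULL,
                               min_single_size = 1L) {
  stopifnot(inherits(mask, "foreground_mask"), inherits(core, "core_estimate"))
  d <- dim(mask)
  if (!identical(d, dim(core$core_mask))) {
    abort("mask and core estimate have different dimensions.")
  }
  connectivity <- check_connectivity(connectivity %||% core$connectivity, d)
  seed <- voxel_index(core$center, d)
  if (!mask[seed]) abort("spheroid center is not a foreground voxel.")
  network <- .cc_flood(unclass(mask), d, seed - 1, connectivity)
  labels <- array(0L, dim = d)
  labels[unclass(mask)] <- 3L
  labels[network] <- 2L
  labels[core$core_mask & network] <- 1L
  if (min_single_size > 1) {
    singles <- labels == 3L
    if (any(singles)) {
      sl <- .cc_label(singles, d, connectivity)
      sizes <- tabulate(sl[sl > 0L])
      drop <- which(sizes < min_single_size)
      if (length(drop)) labels[sl %in% drop] <- 0L
    }
  }
  structure(labels,
    connectivity = connectivity, center = core$center,
    core_radius_est = core$core_radius_est,
    spacing = core$spacing,
    class = c("migration_labels", "array")
  )
}

migration_classes <- c("background", "core", "collective", "single")

#' @export
print.migration_labels <- function(x, ...) {
  n <- tabulate(unclass(x) + 1L, nbins = 4L)
  cat(sprintf(
    "<migration_labels> %s, connectivity %d: %s\n",
    paste(dim(x), collapse = "x"), attr(x, "connectivity"),
    paste(migration_classes, n, sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' Radial migration distances of classified voxels
#'
#' Computes, for every collective and single-cell voxel, its Euclidean
#' physical distance from the spheroid center (the assay's migration
#' distance). With `reference = "surface"` the estimated core radius is
#' subtracted, measuring outgrowth beyond the spheroid edge instead; those
#' distances can be negative for voxels inside the core radius and are
#' clipped at zero when histogrammed. The center reference is the default.
#'
#' @param labels a `migration_labels` array from [classify_migration()].
#' @param core a `core_estimate`; defaults to the center/radius recorded on
#'   `labels`.
#' @param spacing physical voxel spacing; defaults to the spacing recorded on
#'   `labels`.
#' @param reference `"center"` (default) or `"surface"`.
#' @return A tibble with one row per migrating voxel: `class`
#'   (`"collective"` or `"single"`) and `distance` (physical units).
#' @export
radial_distances <- function(labels, core = NULL, spacing = NULL,
                             reference = c("center", "surface")) {
  stopifnot(inherits(labels, "migration_labels"))
  reference <- match.arg(reference)
  center <- if (is.null(core)) attr(labels, "center") else core$center
  radius <- if (is.null(core)) attr(labels, "core_radius_est") else core$core_radius_est
  spacing <- check_spacing(spacing %||% attr(labels, "spacing") %||% 1)
  d <- dim(labels)
  dist <- sqrt(dist2_from(d, center, spacing))
  if (reference == "surface") dist <- dist - radius
  keep <- unclass(labels) >= 2L
  out <- tibble::tibble(
    class = migration_classes[unclass(labels)[keep] + 1L],
    distance = as.vector(dist[keep])
  )
  attr(out, "reference") <- reference
  out
}
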