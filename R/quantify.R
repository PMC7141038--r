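#' Quantify spheroid outgrowth in one image
#'
#' Runs the full analysis on a single stack: foreground segmentation, center
#' and core estimation, connectivity-based classification into collective vs
#' single-cell migration, radial distance measurement, histogramming and
#' scalar summary. All intermediate artifacts are returned for inspection.
#'
#' With `mode = "mip"` the stack is first collapsed to 2D by
#' maximum-intensity projection; `mode = "3d"` (default) analyses the full
#' volume. Projection merges voxels that overlap along the axial direction,
#' so projected counts never exceed the 3D counts.
#'
#' @param stack an [image_stack()] (or a `spheroid_sim`, whose stack is
#'   used).
#' @param mode `"3d"` or `"mip"`.
#' @param threshold_method `"otsu"` or `"fixed"` (see
#'   [segment_foreground()]).
#' @param fixed_threshold threshold for `threshold_method = "fixed"`.
#' @param smooth_sigma dual-scale denoising sigma (voxels); see
#'   [segment_foreground()].
#' @param min_object_size,fill_holes mask cleanup options of
#'   [segment_foreground()]; recommended for noisy images (e.g.
#'   `smooth_sigma = 0.8`, `min_object_size = 5`, `fill_holes = TRUE`).
#' @param connectivity neighbourhood connectivity; default 26 (3D) / 8 (2D).
#' @param reference distance reference, `"center"` (default) or `"surface"`.
#' @param bin_width histogram bin width (physical units).
#' @param max_dist optional histogram upper edge.
#' @param min_single_size minimum single-cell object size (voxels).
#' @return A `migration_result` list: `name`, `mask`, `core`, `labels`,
#'   `distances`, `histogram`, `summary`, `options`. Use [tidy()] for the
#'   histogram, [glance()] for the one-row summary and [autoplot()] to plot.
#' @examples
#' sim <- generate_spheroid_stack(spheroid_params(
#'   shape = c(64, 64, 8),
#'   core_radius = 8, n_sprouts = 2, n_single = 3, sprout_length_mean = 8,
#'   single_dist_range = c(14, 24), seed = 3
#' ))
#' res <- quantify_stack(sim, threshold_method = "fixed", fixed_threshold = 110)
#' glance(res)
#' @export
quantify_stack <- function(stack,
                           mode = c("3d", "mip"),
                           threshold_method = c("otsu", "fixed"),
                           fixed_threshold = NULL,
                           smooth_sigma = 0,
                           min_object_size = 0,
                           fill_holes = FALSE,
                           connectivity = NULL,
                           reference = c("center", "surface"),
                           bin_width = 10,
                           max_dist = NULL,
                           min_single_size = 1L) {
  if (inherits(stack, "spheroid_sim")) stack <- stack$stack
  stopifnot(inherits(stack, "image_stack"))
  mode <- match.arg(mode)
  threshold_method <- match.arg(threshold_method)
  reference <- match.arg(reference)
  if (mode == "mip" && dim(stack)[3] > 1) stack <- max_project(stack)
  mask <- segment_foreground(stack,
    method = threshold_method,
    fixed_threshold = fixed_threshold, smooth_sigma = smooth_sigma,
    min_object_size = min_object_size, fill_holes = fill_holes,
    connectivity = connectivity
  )
  core <- estimate_core(mask, connectivity = connectivity)
  labels <- classify_migration(mask, core,
    connectivity = connectivity,
    min_single_size = min_single_size
  )
  distances <- radial_distances(labels, reference = reference)
  histogram <- migration_histogram(distances,
    bin_width = bin_width,
    max_dist = max_dist
  )
  summary <- summarize_migration(labels, distances)
  structure(
    list(
      name = attr(stack, "name"), mask = mask, core = core, labels = labels,
      distances = distances, histogram = histogram, summary = summary,
      options = list(
        mode = mode, threshold_method = threshold_method,
        threshold_used = attr(mask, "threshold_used"),
        smooth_sigma = smooth_sigma,
        min_object_size = min_object_size, fill_holes = fill_holes,
        connectivity = attr(labels, "connectivity"),
        reference = reference, bin_width = bin_width,
        min_single_size = min_single_size
      )
    ),
    class = "migration_result"
  )
}

#' @export
print.migration_result <- function(x, ...) {
  cat(sprintf(
    "<migration_result> '%s' (%s, threshold %.5g [%s], connectivity %d)\n",
    x$name, x$options$mode, x$options$threshold_used,
    x$options$threshold_method, x$options$connectivity
  ))
  print(x$summary)
  invisible(x)
}

#' Quantify a panel of conditions
#'
#' Applies [quantify_stack()] to every image of a condition panel (e.g. from
#' [generate_condition_panel()], or any tibble with a `condition` column and
#' a list-column of stacks) and returns one tidy summary row per condition.
#'
#' @param panel a tibble with columns `condition` and `sim` (list of
#'   `spheroid_sim` or `image_stack`).
#' @param ... passed on to [quantify_stack()].
#' @return A tibble: `condition`, the [summarize_migration()] columns, and a
#'   `result` list-column with the full `migration_result` objects.
#' @export
quantify_panel <- function(panel, ...) {
  stopifnot(is.data.frame(panel), all(c("condition", "sim") %in% names(panel)))
  results <- purrr::map(panel$sim, quantify_stack, ...)
  summaries <- purrr::map(results, glance)
  dplyr::bind_cols(
    tibble::tibble(condition = panel$condition),
    dplyr::bind_rows(summaries),
    tibble::tibble(result = results)
  )
}

#' @rdname quantify_stack
#' @param x a `migration_result`.
#' @param ... unused.
#' @method tidy migration_result
#' @export
tidy.migration_result <- function(x, ...) {
  out <- x$histogram
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname quantify_stack
#' @method glance migration_result
#' @export
glance.migration_result <- function(x, ...) {
  out <- x$summary
  class(out) <- class(tibble::tibble())
  out
}
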