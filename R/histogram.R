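#' Radial migration histogram
#'
#' Bins the migration distances of collective and single-cell voxels into
#' uniform half-open intervals `[0, w), [w, 2w), ...` — the histogram of
#' "amount of pixels vs migration distance" that summarises one outgrowth
#' image. Surface-referenced distances below zero are counted in the first
#' bin.
#'
#' @param distances tibble from [radial_distances()] (columns `class`,
#'   `distance`).
#' @param bin_width bin width in physical units (default 10, i.e. 10 px at
#'   unit spacing); must be positive.
#' @param max_dist optional upper edge; defaults to the largest observed
#'   distance. Distances beyond `max_dist` are dropped with a warning.
#' @return A `migration_histogram` tibble with integer columns: `bin_lo`,
#'   `bin_hi`, `collective_pixels`, `single_pixels`. Empty input gives a
#'   zero-row tibble.
#' @examples
#' d <- tibble::tibble(
#'   class = c("collective", "collective", "single"),
#'   distance = c(12, 27, 5)
#' )
#' migration_histogram(d, bin_width = 10)
#' @export
migration_histogram <- function(distances, bin_width = 10, max_dist = NULL) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    abort("`bin_width` must be a single positive number.")
  }
  stopifnot(is.data.frame(distances), all(c("class", "distance") %in% names(distances)))
  dd <- dplyr::mutate(distances, distance = pmax(.data$distance, 0))
  if (nrow(dd) == 0) {
    out <- tibble::tibble(
      bin_lo = numeric(), bin_hi = numeric(),
      collective_pixels = integer(), single_pixels = integer()
    )
    return(new_migration_histogram(out, bin_width))
  }
  top <- max_dist %||% max(dd$distance)
  n_bins <- max(1L, as.integer(ceiling((top + 1e-9) / bin_width)))
  if (!is.null(max_dist) && any(dd$distance >= n_bins * bin_width)) {
    warn("distances beyond `max_dist` were dropped from the histogram.")
    dd <- dplyr::filter(dd, .data$distance < n_bins * bin_width)
  }
  bin <- pmin(floor(dd$distance / bin_width), n_bins - 1L) + 1L
  out <- tibble::tibble(
    bin_lo = (seq_len(n_bins) - 1) * bin_width,
    bin_hi = seq_len(n_bins) * bin_width,
    collective_pixels = tabulate(bin[dd$class == "collective"], nbins = n_bins),
    single_pixels = tabulate(bin[dd$class == "single"], nbins = n_bins)
  )
  new_migration_histogram(out, bin_width)
}

new_migration_histogram <- function(tbl, bin_width) {
  tbl$collective_pixels <- as.integer(tbl$collective_pixels)
  tbl$single_pixels <- as.integer(tbl$single_pixels)
  structure(tbl,
    bin_width = bin_width,
    class = c("migration_histogram", class(tibble::tibble()))
  )
}

#' Scalar summary of one quantified outgrowth image
#'
#' Reduces the per-voxel classification and distances to comparable scalars:
#' voxel counts per class, the maximum and mean migration distance per class,
#' and the collective fraction
#' `n_collective / (n_collective + n_single)`. Distance statistics of an
#' empty class, and the collective fraction when no voxel migrated, are `NA`.
#'
#' @param labels a `migration_labels` array from [classify_migration()].
#' @param distances tibble from [radial_distances()].
#' @return A one-row `migration_summary` tibble with columns `n_core`,
#'   `n_collective`, `n_single`, `max_dist_collective`,
#'   `mean_dist_collective`, `max_dist_single`, `mean_dist_single`,
#'   `collective_fraction`.
#' @export
summarize_migration <- function(labels, distances) {
  stopifnot(inherits(labels, "migration_labels"))
  n <- tabulate(unclass(labels) + 1L, nbins = 4L)
  dc <- distances$distance[distances$class == "collective"]
  ds <- distances$distance[distances$class == "single"]
  if (length(dc) != n[3] || length(ds) != n[4]) {
    abort("`distances` is inconsistent with `labels`.")
  }
  stat <- function(x, f) if (length(x)) f(x) else NA_real_
  out <- tibble::tibble(
    n_core = n[2], n_collective = n[3], n_single = n[4],
    max_dist_collective = stat(dc, max),
    mean_dist_collective = stat(dc, mean),
    max_dist_single = stat(ds, max),
    mean_dist_single = stat(ds, mean),
    collective_fraction = if (n[3] + n[4] > 0) n[3] / (n[3] + n[4]) else NA_real_
  )
  class(out) <- c("migration_summary", class(out))
  out
}
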