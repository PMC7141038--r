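#' Read a grayscale TIFF as an image stack
#'
#' Reads a single-channel 8- or 16-bit grayscale TIFF; a single page becomes
#' a one-plane stack, a multi-page file a z-stack (pages are planes). Voxel
#' spacing defaults to 1 per axis and can be overridden; TIFFs carry no
#' reliable 3D spacing, so the override is the normal way to supply a
#' calibrated voxel size.
#'
#' @param path path to the TIFF file.
#' @param spacing_override optional per-axis spacing (row, column, plane).
#' @param name identifier; defaults to the file name.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, spacing_override = NULL, name = NULL) {
  if (!file.exists(path)) abort("file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) abort("unsupported TIFF (", conditionMessage(e), "): ", path)
  )
  if (!is.list(pages)) pages <- list(pages)
  for (pg in pages) {
    if (length(dim(pg)) == 3 && dim(pg)[3] > 1) {
      abort(
        "multichannel input: ", path, " has ", dim(pg)[3],
        " channels; supply a single-channel grayscale image."
      )
    }
  }
  pages <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3) dim(pg) <- dim(pg)[1:2]
    pg
  })
  d2 <- dim(pages[[1]])
  if (!all(vapply(pages, function(pg) identical(dim(pg), d2), logical(1)))) {
    abort("TIFF pages have inconsistent dimensions: ", path)
  }
  arr <- array(unlist(pages, use.names = FALSE), dim = c(d2, length(pages)))
  image_stack(arr,
    spacing = spacing_override %||% 1,
    name = name %||% basename(path)
  )
}

#' Write an image stack (or label volume) as a grayscale TIFF
#'
#' Writes planes as TIFF pages at the requested bit depth. Label arrays are
#' written as-is (small integers), so the file doubles as a label volume
#' readable by ImageJ and similar viewers.
#'
#' @param x an [image_stack()], numeric array, or `migration_labels`.
#' @param path output path.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, bits = 16L) {
  arr <- as_array3d(unclass(x))
  if (!bits %in% c(8, 16)) abort("`bits` must be 8 or 16.")
  maxval <- 2^bits - 1
  if (max(arr) > maxval || min(arr) < 0) {
    abort("intensities outside [0, ", maxval, "]; rescale before writing.")
  }
  pages <- lapply(seq_len(dim(arr)[3]), function(z) arr[, , z] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write / read a migration histogram as CSV
#'
#' The CSV has columns `bin_lo`, `bin_hi`, `collective_pixels`,
#' `single_pixels`; counts are written as integers and a write/read round
#' trip reproduces the histogram exactly. An empty histogram yields a
#' header-only file.
#'
#' @param hist a `migration_histogram` (or the `migration_result` holding
#'   one).
#' @param path output / input path.
#' @return `write_histogram_csv()`: `path` invisibly;
#'   `read_histogram_csv()`: the `migration_histogram` tibble.
#' @export
write_histogram_csv <- function(hist, path) {
  if (inherits(hist, "migration_result")) hist <- hist$histogram
  stopifnot(inherits(hist, "migration_histogram"))
  utils::write.csv(as.data.frame(hist), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  df <- utils::read.csv(path,
    colClasses = c(
      bin_lo = "numeric", bin_hi = "numeric",
      collective_pixels = "integer", single_pixels = "integer"
    )
  )
  bw <- if (nrow(df)) df$bin_hi[1] - df$bin_lo[1] else NA_real_
  new_migration_histogram(tibble::as_tibble(df), bw)
}

#' Write / read a migration summary as JSON
#'
#' Serialises every field of the one-row summary; `NA` statistics (empty
#' classes) are stored as JSON `null`. A write/read round trip reproduces
#' all values exactly.
#'
#' @param summary a `migration_summary` (or a `migration_result`).
#' @param path output / input path.
#' @return `write_summary_json()`: `path` invisibly;
#'   `read_summary_json()`: the `migration_summary` tibble.
#' @export
write_summary_json <- function(summary, path) {
  if (inherits(summary, "migration_result")) summary <- summary$summary
  stopifnot(inherits(summary, "migration_summary"))
  jsonlite::write_json(as.list(summary), path,
    auto_unbox = TRUE, digits = I(17), null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  x <- jsonlite::read_json(path)
  x <- lapply(x, function(v) if (is.null(v)) NA_real_ else v)
  out <- tibble::as_tibble(x)
  for (col in c("n_core", "n_collective", "n_single")) {
    out[[col]] <- as.integer(out[[col]])
  }
  for (col in setdiff(names(out), c("n_core", "n_collective", "n_single"))) {
    out[[col]] <- as.numeric(out[[col]])
  }
  class(out) <- c("migration_summary", class(out))
  out
}

#' Write a generated simulation to disk
#'
#' Saves the intensity stack as a grayscale TIFF, the ground-truth labels as
#' an integer-label TIFF, and a JSON sidecar with the true counts, true
#' center and the full parameter echo.
#'
#' @param sim a `spheroid_sim` from [generate_spheroid_stack()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "spheroid_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- sim$truth$params
  paths <- c(
    image = file.path(dir, paste0(prefix, ".tif")),
    labels = file.path(dir, paste0(prefix, "_labels.tif")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_stack(sim$stack, paths[["image"]], bits = p$bits)
  write_stack(sim$truth$labels, paths[["labels"]], bits = 8L)
  meta <- list(
    true_counts = as.list(sim$truth$true_counts),
    true_center = sim$truth$true_center,
    params = unclass(p)
  )
  jsonlite::write_json(meta, paths[["truth"]],
    auto_unbox = TRUE, digits = I(17)
  )
  invisible(paths)
}
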