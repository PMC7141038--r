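#' Positive-pixel fraction of a grayscale section
#'
#' Threshold-based histomorphometry of stained tissue sections: counts the
#' pixels whose intensity is strictly above a threshold (chosen by the
#' analyst to exclude unspecific staining), optionally restricted to a region
#' of interest, and reports the positive fraction. The threshold is never
#' chosen automatically — use [suggest_threshold()] for a parameter-free Otsu
#' starting point to adjust by eye.
#'
#' @param image a 2D [image_stack()] (single plane) or numeric matrix.
#' @param threshold intensity threshold; pixels with intensity `> threshold`
#'   are positive.
#' @param roi optional logical matrix/array aligned with `image`; only pixels
#'   inside the ROI are counted.
#' @return A one-row `positive_pixel_result` tibble: `n_total`, `n_positive`,
#'   `fraction`, `threshold`.
#' @examples
#' img <- image_stack(matrix(c(0, 10, 200, 255), 2, 2))
#' positive_pixel_fraction(img, threshold = 128)
#' @export
positive_pixel_fraction <- function(image, threshold, roi = NULL) {
  if (!inherits(image, "image_stack")) image <- image_stack(image)
  if (dim(image)[3] != 1) {
    abort("histomorphometry expects a single 2D section, got ", dim(image)[3], " planes.")
  }
  if (missing(threshold) || !is.numeric(threshold) || length(threshold) != 1) {
    abort("`threshold` must be supplied as a single intensity value.")
  }
  v <- as.vector(unclass(image))
  if (!is.null(roi)) {
    roi <- as_array3d(roi)
    storage.mode(roi) <- "logical"
    if (!identical(dim(roi), dim(image))) {
      abort("`roi` dimensions do not match the image.")
    }
    if (!any(roi)) abort("empty roi.")
    v <- v[as.vector(roi)]
  }
  out <- tibble::tibble(
    n_total = length(v),
    n_positive = sum(v > threshold),
    fraction = sum(v > threshold) / length(v),
    threshold = as.numeric(threshold)
  )
  class(out) <- c("positive_pixel_result", class(out))
  out
}

#' @rdname positive_pixel_fraction
#' @export
suggest_threshold <- function(image) {
  if (!inherits(image, "image_stack")) image <- image_stack(image)
  otsu_threshold(image)
}

#' Normalize per-sample values to a control group
#'
#' Divides every value by the mean of the control samples, so the control
#' group has a normalized mean of exactly 1 and all other samples are
#' expressed relative to it. Normalization is scale-invariant: multiplying
#' all input values by a constant leaves the relative values unchanged.
#'
#' @param data a data frame with one row per sample (e.g. stacked
#'   [positive_pixel_fraction()] results).
#' @param value column of values to normalize (tidy-eval).
#' @param control logical expression (tidy-eval, evaluated in `data`)
#'   selecting the control samples.
#' @param name name of the added column.
#' @return `data` with the normalized column appended.
#' @examples
#' df <- tibble::tibble(
#'   condition = c("control", "control", "treated"),
#'   fraction = c(0.18, 0.22, 0.40)
#' )
#' normalize_to_control(df, fraction, condition == "control")
#' @export
normalize_to_control <- function(data, value, control, name = "relative") {
  stopifnot(is.data.frame(data))
  vals <- eval_tidy(enquo(value), data)
  ctrl <- eval_tidy(enquo(control), data)
  if (!is.logical(ctrl) || length(ctrl) != nrow(data)) {
    abort("`control` must select rows of `data` (a logical expression).")
  }
  if (!any(ctrl, na.rm = TRUE)) abort("control group is empty.")
  m <- mean(vals[which(ctrl)])
  if (!is.finite(m) || m <= 0) {
    abort("control group mean must be positive, got ", format(m), ".")
  }
  data[[name]] <- vals / m
  data
}
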