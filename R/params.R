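#' Parameters for the synthetic spheroid-outgrowth generator
#'
#' Bundles and validates every knob of the synthetic image generator: the
#' geometry of the spheroid core, of the multicellular sprouts that remain
#' attached to it (collective migration) and of the detached single cells
#' (mesenchymal-type migration), plus the imaging model (intensities, additive
#' Gaussian noise, optional Gaussian point-spread blur) and the RNG seed.
#'
#' The defaults emulate one field of a spheroid outgrowth assay: a bright,
#' roughly spherical core of a few-hundred-cell microtissue imaged as a
#' confocal z-stack at low magnification, with a handful of sprouts and
#' scattered single cells, on a dim background. All lengths are in voxels.
#'
#' @param shape integer vector, image dimensions `(rows, columns, planes)`;
#'   use `planes = 1` for a 2D image.
#' @param spacing physical voxel size per axis (scalar recycled); only affects
#'   reported distances, never the generated geometry.
#' @param core_radius radius of the spheroid core (voxels), `> 0`.
#' @param center core center, 1-based voxel coordinates, or `"auto"` for the
#'   image center.
#' @param n_sprouts number of sprouts emanating from the core.
#' @param sprout_length_mean,sprout_length_sd sprout length distribution
#'   (normal, truncated at 2 voxels).
#' @param sprout_width sprout thickness (diameter, voxels), `>= 1`.
#' @param n_single number of detached single cells.
#' @param single_radius single-cell radius (voxels).
#' @param single_dist_range length-2 range of single-cell center distances
#'   from the spheroid center (voxels).
#' @param fg_intensity,bg_intensity mean foreground / background intensity
#'   (grey levels); foreground must exceed background.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (grey levels); `0` for noise-free images.
#' @param psf_sigma standard deviation of the Gaussian point-spread blur
#'   (voxels); `0` disables blurring.
#' @param bits bit depth of the simulated detector (8 or 16); intensities are
#'   clipped to `[0, 2^bits - 1]`.
#' @param guarantee_isolation if `TRUE`, single cells are placed with at least
#'   2 voxels clearance from the core + sprout network and from each other, so
#'   each one is its own connected component and the ground-truth
#'   collective/single split is unambiguous.
#' @param seed integer RNG seed; identical parameters (including seed) always
#'   produce bit-identical images.
#' @return A validated `spheroid_params` object (a named list).
#' @seealso [generate_spheroid_stack()], [generate_condition_panel()]
#' @examples
#' p <- spheroid_params(shape = c(64, 64, 8), core_radius = 10, seed = 1)
#' p$center
#' @export
spheroid_params <- function(shape = c(128, 128, 16),
                            spacing = 1,
                            core_radius = 7,
                            center = "auto",
                            n_sprouts = 6,
                            sprout_length_mean = 25,
                            sprout_length_sd = 5,
                            sprout_width = 3,
                            n_single = 12,
                            single_radius = 2,
                            single_dist_range = c(20, 55),
                            fg_intensity = 200,
                            bg_intensity = 20,
                            noise_sd = 0,
                            psf_sigma = 0,
                            bits = 8,
                            guarantee_isolation = TRUE,
                            seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) == 2) shape <- c(shape, 1L)
  if (length(shape) != 3 || anyNA(shape) || any(shape <= 0)) {
    abort("`shape` must be 2 or 3 positive integers (rows, columns, planes).")
  }
  spacing <- check_spacing(spacing)
  if (!is.numeric(core_radius) || core_radius <= 0) {
    abort("`core_radius` must be > 0.")
  }
  if (identical(center, "auto")) {
    center <- floor((shape + 1) / 2)
  }
  center <- as.numeric(center)
  if (length(center) == 2) center <- c(center, 1)
  if (length(center) != 3 || any(center < 1) || any(center > shape)) {
    abort("`center` must lie inside `shape`.")
  }
  if (sprout_width < 1) abort("`sprout_width` must be >= 1 voxel.")
  if (n_sprouts < 0 || n_single < 0) abort("counts must be non-negative.")
  if (single_radius <= 0) abort("`single_radius` must be > 0.")
  single_dist_range <- as.numeric(single_dist_range)
  if (length(single_dist_range) != 2 ||
    single_dist_range[1] > single_dist_range[2]) {
    abort("`single_dist_range` must be c(min, max) with min <= max.")
  }
  if (n_single > 0 && single_dist_range[1] <= core_radius) {
    abort(
      "`single_dist_range` minimum must exceed `core_radius`: ",
      "single cells start outside the spheroid body."
    )
  }
  if (fg_intensity <= bg_intensity) {
    abort("`fg_intensity` must exceed `bg_intensity`.")
  }
  if (bg_intensity < 0 || noise_sd < 0 || psf_sigma < 0) {
    abort("intensities, `noise_sd` and `psf_sigma` must be non-negative.")
  }
  if (!bits %in% c(8, 16)) abort("`bits` must be 8 or 16.")
  if (fg_intensity > 2^bits - 1) {
    abort("`fg_intensity` exceeds the dynamic range of `bits`.")
  }
  # the core (plus a margin of one voxel) must fit in the image
  lo <- center - core_radius
  hi <- center + core_radius
  fits <- all(lo[shape > 1] >= 1) && all(hi[shape > 1] <= shape[shape > 1])
  if (!fits) {
    abort(
      "core of radius ", core_radius, " at center (",
      paste(center, collapse = ", "), ") does not fit in shape (",
      paste(shape, collapse = ", "), ")."
    )
  }
  structure(
    list(
      shape = shape, spacing = spacing, core_radius = core_radius,
      center = center, n_sprouts = as.integer(n_sprouts),
      sprout_length_mean = sprout_length_mean,
      sprout_length_sd = sprout_length_sd,
      sprout_width = sprout_width,
      n_single = as.integer(n_single), single_radius = single_radius,
      single_dist_range = single_dist_range,
      fg_intensity = fg_intensity, bg_intensity = bg_intensity,
      noise_sd = noise_sd, psf_sigma = psf_sigma, bits = bits,
      guarantee_isolation = isTRUE(guarantee_isolation),
      seed = as.integer(seed)
    ),
    class = "spheroid_params"
  )
}

#' @export
print.spheroid_params <- function(x, ...) {
  cat("<spheroid_params>\n")
  cat(sprintf(
    "  shape %s, core radius %.3g at (%s)\n",
    paste(x$shape, collapse = "x"), x$core_radius,
    paste(x$center, collapse = ", ")
  ))
  cat(sprintf(
    "  %d sprouts (length %.3g +/- %.3g, width %.3g), %d single cells (r %.3g, dist %.3g-%.3g)\n",
    x$n_sprouts, x$sprout_length_mean, x$sprout_length_sd, x$sprout_width,
    x$n_single, x$single_radius, x$single_dist_range[1], x$single_dist_range[2]
  ))
  cat(sprintf(
    "  intensities fg %.4g / bg %.4g, noise sd %.3g, psf sigma %.3g, %d-bit, seed %d\n",
    x$fg_intensity, x$bg_intensity, x$noise_sd, x$psf_sigma, x$bits, x$seed
  ))
  invisible(x)
}

#' Modify generator parameters
#'
#' Returns a new [spheroid_params()] object with the given fields replaced and
#' the full validation re-run — the usual way to derive per-condition
#' parameter sets from a base configuration.
#'
#' @param params a `spheroid_params` object.
#' @param ... named fields to override.
#' @return A validated `spheroid_params`.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "spheroid_params"))
  override <- list(...)
  if (length(override) && is.null(names(override))) {
    abort("overrides must be named.")
  }
  unknown <- setdiff(names(override), names(params))
  if (length(unknown)) {
    abort("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  do.call(spheroid_params, modifyList(unclass(params), override))
}
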