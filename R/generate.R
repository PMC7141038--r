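#' Generate a synthetic spheroid-outgrowth image with ground truth
#'
#' Renders one field of a spheroid outgrowth assay from a
#' [spheroid_params()] description: a bright spherical core, contiguous
#' multicellular sprouts seeded on the core surface with random outward
#' directions (the collective-migration phenotype), and isolated single cells
#' placed by rejection sampling at controlled distances from the center (the
#' mesenchymal phenotype). The two-level intensity image then receives
#' additive Gaussian noise, optional Gaussian point-spread blur, and is
#' clipped to the detector range.
#'
#' The returned ground truth holds the exact pre-noise voxel labels
#' (`background`, `core`, `collective`, `single`), their counts, and the true
#' center — the oracle against which the quantification pipeline is
#' validated. Core labels take precedence where a sprout dips inside the core
#' ball. With `guarantee_isolation`, every single cell is a separate connected
#' component with at least 2 voxels clearance from the core + sprout network.
#'
#' Generation is a pure function of `params`: the same parameters (including
#' the seed) give bit-identical output, and the caller's RNG state is left
#' untouched.
#'
#' @param params a [spheroid_params()] object.
#' @return A list of class `spheroid_sim` with elements
#'   \describe{
#'     \item{stack}{the intensity [image_stack()]}
#'     \item{truth}{a `ground_truth` list: `labels` (integer array coded
#'       0 = background, 1 = core, 2 = collective, 3 = single),
#'       `true_counts` (named voxel counts), `true_center` (1-based voxel
#'       coordinates) and the echoed `params`.}
#'   }
#' @examples
#' sim <- generate_spheroid_stack(spheroid_params(
#'   shape = c(64, 64, 8),
#'   core_radius = 8, n_sprouts = 2, n_single = 3,
#'   single_dist_range = c(14, 24), sprout_length_mean = 8, seed = 7
#' ))
#' sim$truth$true_counts
#' @export
generate_spheroid_stack <- function(params) {
  stopifnot(inherits(params, "spheroid_params"))
  with_seed(params$seed, generate_spheroid_impl(params))
}

generate_spheroid_impl <- function(p) {
  d <- p$shape
  is2d <- d[3] == 1
  center <- p$center

  # squared voxel distance (isotropic voxel units) of every voxel from center
  d2 <- dist2_from(d, center)
  core <- d2 <= p$core_radius^2

  # --- sprouts: capsules from just inside the core surface outward ---------
  sprout <- array(FALSE, dim = d)
  sprout_reach <- 0
  if (p$n_sprouts > 0) {
    dirs <- random_directions(p$n_sprouts, is2d)
    lens <- pmax(2, rnorm(p$n_sprouts, p$sprout_length_mean, p$sprout_length_sd))
    half_w <- max(p$sprout_width / 2, 0.5)
    for (i in seq_len(p$n_sprouts)) {
      u <- dirs[i, ]
      p0 <- center + (p$core_radius - 1) * u
      p1 <- center + (p$core_radius + lens[i]) * u
      sprout <- sprout | capsule_mask(d, p0, p1, half_w)
      sprout_reach <- max(sprout_reach, p$core_radius + lens[i] + half_w)
    }
  }
  network <- core | sprout

  # --- single cells: rejection-sampled spheres ----------------------------
  single <- array(FALSE, dim = d)
  if (p$n_single > 0) {
    # distance of every voxel to the network, for the isolation clearance
    clear_net <- if (p$guarantee_isolation) {
      .edt(!network, dim(network), c(1, 1, 1))
    } else {
      NULL
    }
    centers <- place_single_cells(p, d, is2d, clear_net)
    for (i in seq_len(nrow(centers))) {
      single <- single | (dist2_from(d, centers[i, ]) <= p$single_radius^2)
    }
  }

  labels <- array(0L, dim = d)
  labels[single] <- 3L
  labels[sprout] <- 2L
  labels[core] <- 1L # core precedence over sprout bases and any overlap

  fg <- labels > 0L

  img <- array(p$bg_intensity, dim = d)
  img[fg] <- p$fg_intensity
  if (p$noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, p$noise_sd), dim = d)
  }
  if (p$psf_sigma > 0) {
    img <- gaussian_smooth(img, p$psf_sigma)
  }
  img <- pmin(pmax(img, 0), 2^p$bits - 1)

  counts <- tabulate(labels + 1L, nbins = 4L)
  names(counts) <- c("background", "core", "collective", "single")

  structure(
    list(
      stack = image_stack(img, spacing = p$spacing, name = sprintf("sim_seed%d", p$seed)),
      truth = structure(
        list(
          labels = labels, true_counts = counts,
          true_center = center, params = p
        ),
        class = "ground_truth"
      )
    ),
    class = "spheroid_sim"
  )
}

# n unit vectors, uniform on the sphere (or circle when is2d)
random_directions <- function(n, is2d) {
  if (is2d) {
    th <- runif(n, 0, 2 * pi)
    cbind(sin(th), cos(th), 0)
  } else {
    z <- runif(n, -1, 1)
    th <- runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    cbind(r * sin(th), r * cos(th), z)
  }
}

# voxels within `radius` of the segment p0--p1 (isotropic voxel units),
# computed on the segment's bounding box only
capsule_mask <- function(d, p0, p1, radius) {
  mask <- array(FALSE, dim = d)
  lo <- pmax(floor(pmin(p0, p1) - radius), 1)
  hi <- pmin(ceiling(pmax(p0, p1) + radius), d)
  if (any(lo > hi)) {
    return(mask)
  }
  ys <- lo[1]:hi[1]
  xs <- lo[2]:hi[2]
  zs <- lo[3]:hi[3]
  g <- expand.grid(y = ys, x = xs, z = zs)
  v <- cbind(g$y, g$x, g$z)
  seg <- p1 - p0
  len2 <- sum(seg^2)
  w <- sweep(v, 2, p0)
  tt <- if (len2 > 0) pmin(pmax(w %*% seg / len2, 0), 1) else 0
  nearest <- outer(as.vector(tt), seg) # n x 3
  dist2 <- rowSums((w - nearest)^2)
  inside <- dist2 <= radius^2
  sub <- array(inside, dim = c(length(ys), length(xs), length(zs)))
  mask[ys, xs, zs] <- sub
  mask
}

# rejection-sample single-cell centers; returns an n x 3 matrix of 1-based
# integer voxel coordinates
place_single_cells <- function(p, d, is2d, clear_net) {
  # clearance, center to nearest network voxel: cell radius + 2 voxel gap +
  # 1 voxel rasterisation margin
  min_clear <- p$single_radius + 3
  min_pair <- 2 * p$single_radius + 3
  margin <- ceiling(p$single_radius)
  accepted <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  max_tries <- 2000L * p$n_single
  while (nrow(accepted) < p$n_single) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(
        "could not place ", p$n_single, " isolated single cells in shape (",
        paste(d, collapse = ", "), ") within `single_dist_range` [",
        paste(p$single_dist_range, collapse = ", "),
        "]; enlarge the image or widen the range."
      )
    }
    u <- random_directions(1, is2d)[1, ]
    r <- runif(1, p$single_dist_range[1], p$single_dist_range[2])
    ctr <- round(p$center + r * u)
    if (is2d) ctr[3] <- 1
    lo_ok <- all(ctr[d > 1] - margin >= 1)
    hi_ok <- all((ctr + margin)[d > 1] <= d[d > 1])
    if (!lo_ok || !hi_ok) next
    rr <- sqrt(sum((ctr - p$center)^2))
    if (rr < p$single_dist_range[1] || rr > p$single_dist_range[2]) next
    if (p$guarantee_isolation) {
      if (clear_net[voxel_index(ctr, d)] < min_clear) next
      if (nrow(accepted) > 0) {
        dd <- sqrt(rowSums(sweep(accepted, 2, ctr)^2))
        if (any(dd < min_pair)) next
      }
    }
    accepted <- rbind(accepted, ctr)
  }
  accepted
}

#' @export
print.spheroid_sim <- function(x, ...) {
  cat("<spheroid_sim>\n")
  print(x$stack)
  cat(
    "  truth:",
    paste(names(x$truth$true_counts), x$truth$true_counts,
      sep = "=", collapse = ", "
    ), "\n"
  )
  invisible(x)
}

# Evaluate `code` under `seed` and restore the caller's RNG state after.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a panel of synthetic conditions
#'
#' Produces one seeded synthetic image per experimental condition, mimicking a
#' growth-factor screen in which each factor shifts the balance between
#' collective sprouting and single-cell dispersal. Each condition is a named
#' list of [spheroid_params()] overrides applied to `base`; unless an override
#' sets its own `seed`, a per-condition seed is derived deterministically from
#' `base$seed` and the condition's position, so conditions differ but the
#' whole panel is reproducible.
#'
#' @param base a [spheroid_params()] object shared by all conditions.
#' @param conditions a named list; each element is a (possibly empty) named
#'   list of parameter overrides. Condition names must be unique.
#' @return A tibble with one row per condition: `condition`, `params`
#'   (list of `spheroid_params`), `sim` (list of `spheroid_sim`).
#' @examples
#' base <- spheroid_params(
#'   shape = c(64, 64, 8), core_radius = 8,
#'   n_sprouts = 2, n_single = 2, sprout_length_mean = 8,
#'   single_dist_range = c(14, 24), seed = 11
#' )
#' panel <- generate_condition_panel(base, list(
#'   control = list(n_sprouts = 0, n_single = 0),
#'   `FGF-like` = list(n_sprouts = 4),
#'   `PDGF-like` = list(n_single = 6)
#' ))
#' panel$condition
#' @export
generate_condition_panel <- function(base, conditions) {
  stopifnot(inherits(base, "spheroid_params"))
  if (length(conditions) == 0) {
    return(tibble::tibble(
      condition = character(), params = list(), sim = list()
    ))
  }
  nm <- names(conditions)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    abort("every condition must be named.")
  }
  if (anyDuplicated(nm)) {
    abort(
      "duplicate condition name(s): ",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    )
  }
  sims <- purrr::imap(conditions, function(override, name) {
    i <- match(name, nm)
    pars <- do.call(update_params, c(list(base), override))
    if (!("seed" %in% names(override))) {
      pars <- update_params(pars, seed = derive_seed(base$seed, i))
    }
    list(params = pars, sim = generate_spheroid_stack(pars))
  })
  tibble::tibble(
    condition = nm,
    params = purrr::map(sims, "params"),
    sim = purrr::map(sims, "sim")
  )
}

# deterministic per-condition seed, kept within 32-bit integer range
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 7919 + index * 104729) %% 2147483647)
}
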