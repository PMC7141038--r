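# Small-grid reference case: 3x3 core block at the center of a 9x9 image, a
# one-wide 3-pixel arm, and one isolated pixel. Hand-checkable on the grid:
# arm pixels at distances 2, 3, 4 from the center; the isolated pixel at
# (2,2) sits sqrt(18) ~ 4.243 away.
make_grid9 <- function() {
  m <- array(FALSE, dim = c(9, 9, 1))
  m[4:6, 4:6, 1] <- TRUE
  m[5, 7:9, 1] <- TRUE
  m[2, 2, 1] <- TRUE
  m
}

grid_core <- function(m) suppressMessages(estimate_core(as_mask_for_test(m)))

test_that("arm pixels are collective and the isolated pixel is single", {
  m <- make_grid9()
  core <- grid_core(m)
  expect_equal(core$center, c(5, 5, 1))
  lab <- classify_migration(as_mask_for_test(m), core)
  expect_equal(sum(lab == 2L), 3L) # (5,7) (5,8) (5,9) beyond the core radius
  expect_equal(sum(lab == 3L), 1L)
  expect_true(lab[2, 2, 1] == 3L)
  # agreement with the flood-fill oracle on the same grid
  net <- oracle_flood(m, core$center, 8)
  expect_identical(as.vector(unclass(lab) %in% c(1L, 2L)), as.vector(net))
})

test_that("the small-grid summary matches hand-computed values", {
  m <- make_grid9()
  core <- grid_core(m)
  lab <- classify_migration(as_mask_for_test(m), core)
  dist <- radial_distances(lab)
  s <- summarize_migration(lab, dist)
  expect_equal(s$n_collective, 3L)
  expect_equal(s$n_single, 1L)
  expect_equal(s$max_dist_collective, 4) # arm tip (5,9) is 4 from (5,5)
  expect_equal(s$max_dist_single, sqrt(18), tolerance = 1e-12)
  expect_equal(s$collective_fraction, 0.75)
})

test_that("core-only masks have no migrating voxels and undefined fraction", {
  m <- array(FALSE, dim = c(15, 15, 1))
  m[spheromigrate:::dist2_from(dim(m), c(8, 8, 1)) <= 9] <- TRUE
  core <- estimate_core(as_mask_for_test(m))
  lab <- classify_migration(as_mask_for_test(m), core)
  dist <- radial_distances(lab)
  s <- summarize_migration(lab, dist)
  expect_equal(s$n_collective, 0L)
  expect_equal(s$n_single, 0L)
  expect_true(is.na(s$collective_fraction))
  expect_true(is.na(s$max_dist_collective))
})

test_that("radial distances follow Euclidean geometry and the reference mode", {
  lab <- array(0L, dim = c(9, 9, 9))
  lab[4 + 3, 4 + 4, 4] <- 2L # offset (3, 4, 0) from center
  lab <- structure(lab,
    connectivity = 26L, center = c(4, 4, 4), core_radius_est = 5,
    spacing = c(1, 1, 1), class = c("migration_labels", "array")
  )
  d <- radial_distances(lab)
  expect_equal(d$distance, 5)
  dsurf <- radial_distances(lab, reference = "surface")
  expect_equal(dsurf$distance, 0)
  # anisotropic spacing scales per axis
  attr(lab, "spacing") <- c(2, 1, 1)
  lab2 <- array(0L, dim = c(9, 9, 9))
  lab2[5, 4, 4] <- 2L # offset (1, 0, 0)
  attributes(lab2) <- attributes(lab)
  expect_equal(radial_distances(lab2)$distance, 2)
})

test_that("histogram bins are half-open, lower-inclusive and conservative", {
  d <- tibble::tibble(
    class = c("collective", "collective", "single"),
    distance = c(12, 27, 5)
  )
  h <- migration_histogram(d, bin_width = 10)
  expect_equal(h$bin_lo, c(0, 10, 20))
  expect_equal(h$collective_pixels, c(0L, 1L, 1L))
  expect_equal(h$single_pixels, c(1L, 0L, 0L))
  # boundary value 10 falls in [10, 20)
  h2 <- migration_histogram(
    tibble::tibble(class = "single", distance = 10), 10
  )
  expect_equal(h2$single_pixels, c(0L, 1L))
  expect_error(migration_histogram(d, bin_width = 0), "positive")
})

test_that("empty distance sets give an empty histogram", {
  h <- migration_histogram(
    tibble::tibble(class = character(), distance = numeric()), 10
  )
  expect_equal(nrow(h), 0L)
  expect_named(h, c("bin_lo", "bin_hi", "collective_pixels", "single_pixels"))
})

test_that("histogram counts are conserved for random distances", {
  set.seed(31)
  d <- tibble::tibble(
    class = sample(c("collective", "single"), 1000, replace = TRUE),
    distance = runif(1000, 0, 100)
  )
  h <- migration_histogram(d, bin_width = 10)
  expect_equal(sum(h$collective_pixels), sum(d$class == "collective"))
  expect_equal(sum(h$collective_pixels) + sum(h$single_pixels), 1000L)
})

test_that("classification equals generator ground truth on noise-free stacks", {
  p <- spheroid_params(
    shape = c(96, 96, 16), core_radius = 7, n_sprouts = 4,
    sprout_length_mean = 12, n_single = 6, single_radius = 2,
    single_dist_range = c(18, 40), noise_sd = 0,
    guarantee_isolation = TRUE, seed = 21
  )
  sim <- generate_spheroid_stack(p)
  res <- quantify_quiet(sim, threshold_method = "fixed", fixed_threshold = 110)
  expect_identical(strip_attrs(res$labels), sim$truth$labels)
})

test_that("doubling the spacing doubles distance statistics, not counts", {
  p <- spheroid_params(
    shape = c(64, 64, 14), core_radius = 6, n_sprouts = 2,
    sprout_length_mean = 8, n_single = 3, single_radius = 2,
    single_dist_range = c(12, 24), noise_sd = 0, seed = 13
  )
  s1 <- glance(quantify_quiet(generate_spheroid_stack(p),
    threshold_method = "fixed", fixed_threshold = 110
  ))
  p2 <- update_params(p, spacing = 2)
  s2 <- glance(quantify_quiet(generate_spheroid_stack(p2),
    threshold_method = "fixed", fixed_threshold = 110
  ))
  expect_equal(s2$n_core, s1$n_core)
  expect_equal(s2$n_collective, s1$n_collective)
  expect_equal(s2$n_single, s1$n_single)
  expect_equal(s2$max_dist_collective, 2 * s1$max_dist_collective)
  expect_equal(s2$mean_dist_single, 2 * s1$mean_dist_single)
})

test_that("small single objects can be suppressed by the size filter", {
  m <- array(FALSE, dim = c(21, 21, 1))
  m[spheromigrate:::dist2_from(dim(m), c(11, 11, 1)) <= 9] <- TRUE
  m[2, 2, 1] <- TRUE # 1-voxel speck
  m[18:19, 18, 1] <- TRUE # 2-voxel object
  core <- grid_core(m)
  lab_all <- classify_migration(as_mask_for_test(m), core)
  expect_equal(sum(lab_all == 3L), 3L)
  lab_flt <- classify_migration(as_mask_for_test(m), core, min_single_size = 2)
  expect_equal(sum(lab_flt == 3L), 2L)
  expect_equal(lab_flt[2, 2, 1], 0L)
})

test_that("MIP counts never exceed 3D counts", {
  p <- spheroid_params(
    shape = c(64, 64, 14), core_radius = 6, n_sprouts = 3,
    sprout_length_mean = 8, n_single = 4, single_radius = 2,
    single_dist_range = c(12, 26), noise_sd = 0, seed = 17
  )
  sim <- generate_spheroid_stack(p)
  r3 <- quantify_quiet(sim, threshold_method = "fixed", fixed_threshold = 110)
  rm_ <- quantify_quiet(sim,
    mode = "mip",
    threshold_method = "fixed", fixed_threshold = 110
  )
  g3 <- glance(r3)
  gm <- glance(rm_)
  expect_lte(gm$n_collective + gm$n_single + gm$n_core, g3$n_collective + g3$n_single + g3$n_core)
  expect_lte(gm$n_single, g3$n_single)
})

test_that("tidy and glance expose histogram and summary as plain tibbles", {
  p <- spheroid_params(
    shape = c(48, 48, 12), core_radius = 5, n_sprouts = 2,
    sprout_length_mean = 6, n_single = 2, single_radius = 2,
    single_dist_range = c(10, 18), noise_sd = 0, seed = 9
  )
  res <- quantify_quiet(generate_spheroid_stack(p),
    threshold_method = "fixed", fixed_threshold = 110
  )
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "migration_histogram"))
  expect_equal(sum(td$collective_pixels), glance(res)$n_collective)
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  pl <- autoplot(res)
  expect_s3_class(pl, "ggplot")
})
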