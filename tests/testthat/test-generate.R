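small_params <- function(...) {
  defaults <- list(
    shape = c(64, 64, 16), core_radius = 7, n_sprouts = 3,
    sprout_length_mean = 10, sprout_length_sd = 2, sprout_width = 3,
    n_single = 5, single_radius = 2, single_dist_range = c(14, 26),
    noise_sd = 0, seed = 42
  )
  do.call(spheroid_params, utils::modifyList(defaults, list(...)))
}

test_that("parameter validation rejects impossible geometry", {
  expect_error(spheroid_params(shape = c(0, 10, 10)), "positive")
  expect_error(spheroid_params(shape = c(20, 20, 20), core_radius = 15), "does not fit")
  expect_error(spheroid_params(fg_intensity = 10, bg_intensity = 20), "exceed")
  expect_error(spheroid_params(core_radius = -1), "core_radius")
  expect_error(
    spheroid_params(single_dist_range = c(3, 10), core_radius = 7),
    "single_dist_range"
  )
  expect_error(small_params(sprout_width = 0.5), "sprout_width")
})

test_that("update_params re-validates and rejects unknown fields", {
  p <- small_params()
  p2 <- update_params(p, n_single = 9)
  expect_equal(p2$n_single, 9L)
  expect_equal(p2$core_radius, p$core_radius)
  expect_error(update_params(p, not_a_field = 1), "unknown parameter")
  expect_error(update_params(p, core_radius = 13), "does not fit")
})

test_that("no-outgrowth parameters yield only background and core", {
  sim <- generate_spheroid_stack(small_params(n_sprouts = 0, n_single = 0))
  expect_setequal(unique(as.vector(sim$truth$labels)), c(0L, 1L))
  expect_identical(sim$truth$true_counts[["collective"]], 0L)
  expect_identical(sim$truth$true_counts[["single"]], 0L)
})

test_that("generation is a pure function of the parameters", {
  p <- small_params(noise_sd = 12, psf_sigma = 0.7)
  a <- generate_spheroid_stack(p)
  b <- generate_spheroid_stack(p)
  expect_identical(unclass(a$stack), unclass(b$stack))
  expect_identical(a$truth$labels, b$truth$labels)
  # caller's RNG stream is not disturbed
  set.seed(99)
  x1 <- runif(3)
  set.seed(99)
  invisible(generate_spheroid_stack(p))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("true_counts sum to the voxel total", {
  for (s in c(1, 2, 3)) {
    sim <- generate_spheroid_stack(small_params(seed = s, noise_sd = 15))
    expect_identical(sum(sim$truth$true_counts), as.integer(prod(dim(sim$stack))))
    expect_identical(
      as.vector(table(factor(sim$truth$labels, 0:3))),
      as.vector(sim$truth$true_counts)
    )
  }
})

test_that("isolated single cells form exactly n_single + 1 components", {
  p <- spheroid_params(
    shape = c(96, 96, 16), core_radius = 7, n_sprouts = 2,
    sprout_length_mean = 8, n_single = 12, single_radius = 2,
    single_dist_range = c(18, 40), noise_sd = 0,
    guarantee_isolation = TRUE, seed = 7
  )
  sim <- generate_spheroid_stack(p)
  fg <- sim$truth$labels > 0L
  expect_equal(oracle_n_components(fg, 26), 13L)
  # every single voxel is disconnected from the component holding the center
  net <- oracle_flood(fg, sim$truth$true_center, 26)
  expect_false(any(net & sim$truth$labels == 3L))
  expect_true(all(net[sim$truth$labels %in% c(1L, 2L)]))
})

test_that("noise-free foreground is recovered exactly by midpoint threshold", {
  p <- small_params(psf_sigma = 0)
  sim <- generate_spheroid_stack(p)
  thr <- (p$fg_intensity + p$bg_intensity) / 2
  expect_identical(unclass(sim$stack) >= thr, sim$truth$labels > 0L)
})

test_that("2D generation is the one-plane case of the 3D path", {
  p <- spheroid_params(
    shape = c(64, 64, 1), core_radius = 7, n_sprouts = 2,
    sprout_length_mean = 8, n_single = 3, single_radius = 2,
    single_dist_range = c(14, 26), noise_sd = 0, seed = 3
  )
  sim <- generate_spheroid_stack(p)
  expect_equal(dim(sim$stack)[3], 1L)
  expect_equal(oracle_n_components(sim$truth$labels > 0L, 8), 4L)
})

test_that("condition panel derives distinct, seeded, reproducible images", {
  base <- small_params()
  specs <- list(
    control = list(n_sprouts = 0, n_single = 0),
    `FGF-like` = list(n_sprouts = 5, sprout_length_mean = 14),
    `PDGF-like` = list(n_single = 10)
  )
  panel <- generate_condition_panel(base, specs)
  expect_equal(panel$condition, names(specs))
  counts <- t(vapply(panel$sim, function(s) s$truth$true_counts, integer(4)))
  expect_identical(counts[1, "collective"] + counts[1, "single"], 0L)
  expect_gt(counts[2, "collective"], counts[1, "collective"])
  expect_gt(counts[3, "single"], counts[2, "single"])
  # reproducible
  panel2 <- generate_condition_panel(base, specs)
  expect_identical(
    unclass(panel$sim[[2]]$stack),
    unclass(panel2$sim[[2]]$stack)
  )
})

test_that("empty and duplicate condition lists are handled", {
  base <- small_params()
  expect_equal(nrow(generate_condition_panel(base, list())), 0L)
  expect_error(
    generate_condition_panel(base, list(a = list(), a = list())),
    "duplicate"
  )
})

test_that("a 20-condition panel yields pairwise non-identical images", {
  base <- small_params(noise_sd = 10)
  specs <- setNames(
    replicate(20, list(), simplify = FALSE),
    paste0("factor_", 1:20)
  )
  panel <- generate_condition_panel(base, specs)
  stacks <- lapply(panel$sim, function(s) unclass(s$stack))
  for (i in 1:19) {
    for (j in (i + 1):20) {
      expect_false(identical(stacks[[i]], stacks[[j]]))
    }
  }
})
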