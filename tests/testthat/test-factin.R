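test_that("trace sampling averages a voxel-space sphere and flags out-of-bounds nodes", {
  # constant field: every sample equals the constant
  tr <- line_tree(5, spacing = 2)
  f <- labeled_volume(array(7, c(12, 5, 5)))
  s <- sample_along_trace(tr, f, radius_vox = 1, origin = c(0, -2.5, -2.5))
  expect_equal(s$raw, rep(7, 5))

  # single bright voxel at a node: mean over the 7-voxel sphere (radius 1)
  a <- array(0, c(12, 5, 5))
  a[3, 3, 3] <- 70
  f2 <- labeled_volume(a)
  tr2 <- neurite_tree(data.frame(id = 1:2, x = c(2.5, 4.5), y = 0.5, z = 0.5,
                                 radius = 1, parent = c(-1L, 1L)))
  s2 <- sample_along_trace(tr2, f2, 1, origin = c(0, -2, -2))
  expect_equal(s2$raw[1], sphere_sample_oracle(a, c(3, 3, 3), 1))
  expect_equal(s2$raw[1], 10)   # 70 spread over 7 in-sphere voxels

  # radius 0: nearest-voxel lookup
  s3 <- sample_along_trace(tr2, f2, 0, origin = c(0, -2, -2))
  expect_equal(s3$raw, c(70, 0))

  # node outside the field is marked missing
  tr3 <- neurite_tree(data.frame(id = 1:2, x = c(2.5, 100), y = 0.5, z = 0.5,
                                 radius = 1, parent = c(-1L, 1L)))
  s4 <- sample_along_trace(tr3, f2, 1, origin = c(0, -2, -2))
  expect_true(s4$missing[2])
  expect_true(is.na(s4$raw[2]))
})

test_that("per-axon normalization is min-max and affine-invariant", {
  s <- data.frame(node = 1:3, raw = c(10, 20, 30), missing = FALSE)
  p <- normalize_profile(s)
  expect_equal(p$normalized, c(0, 0.5, 1))
  set.seed(71)
  s2 <- data.frame(node = 1:20, raw = rnorm(20), missing = FALSE)
  p2 <- normalize_profile(s2)
  s3 <- s2; s3$raw <- 3 * s2$raw + 11
  expect_equal(normalize_profile(s3)$normalized, p2$normalized,
               tolerance = 1e-12)
  expect_error(normalize_profile(data.frame(node = 1:3, raw = 5,
                                            missing = FALSE)), "degenerate")
  # missing samples do not set the extremes
  s4 <- rbind(s, data.frame(node = 4, raw = NA, missing = TRUE))
  expect_equal(normalize_profile(s4)$normalized, c(0, 0.5, 1, NA))
})

test_that("segment density integrates the profile: flat, ramp, oracle and concatenation", {
  tr <- line_tree(11, spacing = 1)
  flat <- data.frame(node = 1:11, raw = 1, missing = FALSE)
  prof <- flat
  prof$normalized <- 0.37
  class(prof) <- c("factin_profile", "data.frame")
  d <- segment_density(prof, tr, 1:11)
  expect_equal(d$density, 0.37)
  expect_equal(d$length, 10)

  ramp <- prof
  ramp$normalized <- seq(0, 1, by = 0.1)
  expect_equal(segment_density(ramp, tr, 1:11)$density, 0.5)

  set.seed(72)
  rnd <- prof
  rnd$normalized <- runif(11)
  v <- rnd$normalized
  trap <- sum(0.5 * (v[-1] + v[-11]) * 1) / 10
  expect_equal(segment_density(rnd, tr, 1:11)$density, trap)
  # node-sum variant behind its flag
  expect_equal(segment_density(rnd, tr, 1:11, method = "node_sum")$density,
               sum(v) / 10)

  # concatenation: whole-segment density is the length-weighted mean of halves
  d1 <- segment_density(rnd, tr, 1:6)
  d2 <- segment_density(rnd, tr, 6:11)
  whole <- segment_density(rnd, tr, 1:11)
  expect_equal(whole$density,
               (d1$density * d1$length + d2$density * d2$length) /
                 (d1$length + d2$length), tolerance = 1e-12)
  expect_error(segment_density(rnd, tr, 3L), "at least 2")
})

test_that("branch densities stay in [0,1] and are invariant to affine field transforms", {
  sim <- gen_axon_with_field(axon_sim_config(seed = 73))
  m <- axon_morphometry(sim$tree, sim$regions)
  s <- sample_along_trace(sim$tree, sim$field, 1, sim$origin)
  prof <- normalize_profile(s)
  dens <- branch_densities(sim$tree, prof, m$records,
                           sim$regions$pn_dendrites)
  ok <- !is.na(dens$density_whole)
  expect_true(all(dens$density_whole[ok] >= 0 & dens$density_whole[ok] <= 1))
  # affine transform of the raw field leaves densities unchanged
  f2 <- labeled_volume(2.5 * sim$field$voxels - 40, sim$field$voxel_size)
  prof2 <- normalize_profile(sample_along_trace(sim$tree, f2, 1, sim$origin))
  dens2 <- branch_densities(sim$tree, prof2, m$records,
                            sim$regions$pn_dendrites)
  expect_equal(dens2$density_whole, dens$density_whole, tolerance = 1e-10)
  # sub-segment lengths of contacting branches sum to the branch length
  # (edge classes partition the subtree edges)
})

test_that("density comparisons handle identical classes and degenerate pairs", {
  d0 <- data.frame(contacts_pn = rep(c(TRUE, FALSE), each = 4),
                   density_whole = rep(c(0.2, 0.4, 0.6, 0.8), 2),
                   density_plus = NA_real_, density_minus = NA_real_)
  r <- factin_compare(d0)
  expect_gt(r$between$p, 0.99)

  d1 <- data.frame(contacts_pn = TRUE,
                   density_whole = c(0.5, 0.6, 0.7),
                   density_plus = c(0.5, 0.6, 0.7),
                   density_minus = c(0.3, 0.4, 0.5))   # constant diff 0.2
  expect_warning(r1 <- factin_compare(d1), "zero-variance")
  expect_equal(r1$within$p, 0)
  expect_equal(r1$within$mean_diff, 0.2)

  # no contacting branches: between comparison skipped with a notice
  d2 <- data.frame(contacts_pn = FALSE, density_whole = c(0.1, 0.2),
                   density_plus = NA_real_, density_minus = NA_real_)
  expect_message(r2 <- factin_compare(d2), "skipped")
  expect_null(r2$between)
})

test_that("a planted contact-zone boost raises (+) over (-) densities in most axons", {
  hits <- 0L
  n_ax <- 20L
  usable <- 0L
  for (i in seq_len(n_ax)) {
    sim <- gen_axon_with_field(axon_sim_config(seed = 7000L + i,
                                               voxel_size = 2))
    m <- axon_morphometry(sim$tree, sim$regions)
    prof <- normalize_profile(
      sample_along_trace(sim$tree, sim$field, 1, sim$origin))
    dens <- branch_densities(sim$tree, prof, m$records,
                             sim$regions$pn_dendrites)
    ok <- dens$contacts_pn %in% TRUE & !is.na(dens$density_plus) &
      !is.na(dens$density_minus)
    if (!any(ok)) next
    usable <- usable + 1L
    if (mean(dens$density_plus[ok] - dens$density_minus[ok]) > 0)
      hits <- hits + 1L
  }
  expect_gte(usable, 15L)
  expect_gte(hits / usable, 0.9)
})
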