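test_that("contrast vectors are the exact factorial weights", {
  expect_identical(unname(contrast_vector("all_sound_vs_silence")),
                   c(1L, 1L, 1L, 1L, -4L))
  expect_identical(unname(contrast_vector("meaningless_vs_silence")),
                   c(0L, 0L, 1L, 1L, -2L))
  expect_identical(unname(contrast_vector("category_animal")),
                   c(1L, -1L, -1L, 1L, 0L))
  expect_identical(contrast_vector("category_tool"),
                   -contrast_vector("category_animal"))
  # every contrast not involving the silence baseline sums to zero
  for (nm in c("meaningful_vs_meaningless", "semantic_animal",
               "semantic_tool", "category_animal", "category_tool"))
    expect_equal(sum(contrast_vector(nm)), 0)
  expect_error(contrast_vector("nope"), "unknown contrast")
  # duplicated across runs with zeros for the six motion regressors
  ex <- expand_contrast(contrast_vector("category_animal"))
  expect_length(ex, 22)
  expect_equal(ex[1:5], ex[12:16])
  expect_equal(unname(ex[6:11]), numeric(6))
})

test_that("the Welch t map is zero for identical constant groups", {
  m <- stat_map(array(3, c(4, 4, 4)))
  res <- welch_group_t_map(list(m, m), list(m, m))
  expect_true(all(res$t$values == 0))
  expect_error(welch_group_t_map(list(m), list(m, m)), "at least 2")
})

test_that("a planted spherical effect raises |t| inside the sphere", {
  sim <- simulate_group_maps(8, dims = c(16, 16, 16),
                             effect_regions = list(
                               list(center = c(0, 0, 0), radius = 6,
                                    effect = 1)),
                             effect_size = 1.5, noise_sd = 1, seed = 31)
  res <- welch_group_t_map(sim$groupA, sim$groupB)
  grid <- as.matrix(expand.grid(1:16, 1:16, 1:16))
  mm <- (grid - 1) * 2 - 15
  inside <- rowSums(mm^2) <= 36
  expect_gt(mean(abs(res$t$values[inside])),
            mean(abs(res$t$values[!inside])) + 1)
  # and cluster formation recovers a cluster overlapping the sphere
  thr <- p_to_t_threshold(0.001, res$df)
  cl <- form_clusters(res$t, thr)
  expect_gt(length(cl), 0)
  peak_in_sphere <- sum(cl[[1]]$peak_mm^2) <= 36
  expect_true(peak_in_sphere)
})

test_that("null simulations give the nominal false-positive rate", {
  sim <- simulate_group_maps(10, dims = c(22, 22, 21), effect_size = 0,
                             seed = 32)
  res <- welch_group_t_map(sim$groupA, sim$groupB)
  pv <- 2 * stats::pt(abs(res$t$values), res$df, lower.tail = FALSE)
  rate <- mean(pv < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
  # same seed reproduces the same maps
  sim2 <- simulate_group_maps(10, dims = c(22, 22, 21), effect_size = 0,
                              seed = 32)
  expect_identical(sim$groupA[[1]]$values, sim2$groupA[[1]]$values)
})

test_that("trivial cluster configurations label correctly", {
  v <- array(0, c(5, 5, 5))
  expect_length(form_clusters(stat_map(v), 1), 0)
  v[2, 2, 2] <- 5
  cl <- form_clusters(stat_map(v), 1)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$extent_k, 1)
  # two diagonal-touching voxels: one cluster under 18, two under 6
  v[3, 3, 2] <- 5
  expect_length(form_clusters(stat_map(v), 1, 18), 1)
  expect_length(form_clusters(stat_map(v), 1, 6), 2)
  expect_error(form_clusters(stat_map(v), 1, 10), "connectivity")
})

test_that("cluster labelling matches the graph-components oracle", {
  skip_if_not_installed("igraph")
  for (seed in 41:43) {
    set.seed(seed)
    v <- array(rnorm(16^3), c(16, 16, 16))
    m <- stat_map(v)
    for (conn in c(6L, 18L, 26L)) {
      cl <- form_clusters(m, 0.8, conn)
      sizes <- sort(vapply(cl, `[[`, 0L, "extent_k"), decreasing = TRUE)
      expect_identical(as.integer(sizes),
                       igraph_cluster_sizes(v, 0.8, conn))
    }
  }
})

test_that("voxel categorisation follows the control-group sign", {
  mask <- array(0, c(6, 6, 6)); mask[2:5, 2:5, 2:5] <- 1
  pos <- stat_map(array(1, c(6, 6, 6)))
  lab <- categorise_interaction_voxels(mask, pos)
  expect_true(all(lab$labels[mask == 1] == lab$legend[["cyan"]]))
  expect_true(all(lab$labels[mask == 0] == lab$legend[["outside"]]))
  neg <- stat_map(array(-1, c(6, 6, 6)))
  lab2 <- categorise_interaction_voxels(mask, neg)
  expect_true(all(lab2$labels[mask == 1] == lab2$legend[["magenta"]]))
  # mixed-sign map: labels equal an independent per-voxel sign computation
  set.seed(44)
  ctrl <- stat_map(array(rnorm(216), c(6, 6, 6)))
  lab3 <- categorise_interaction_voxels(mask, ctrl)
  oracle <- ifelse(ctrl$values > 0, 1L, ifelse(ctrl$values < 0, 2L, 3L))
  oracle[mask == 0] <- 0L
  expect_identical(lab3$labels, oracle)
  expect_error(categorise_interaction_voxels(array(2, c(6, 6, 6)), pos),
               "binary")
})

test_that("focus sampling honours the affine", {
  aff <- modfilt:::default_affine(c(10, 10, 10))
  const <- stat_map(array(7, c(10, 10, 10)), aff)
  fs <- focus_set(c("a", "b"), rbind(c(-4, 0, 2), c(6, -2, 0)))
  out <- sample_foci(list(const, const), fs)
  expect_true(all(out$values == 7))
  # a value planted at one focus voxel is seen only by that focus
  v <- array(0, c(10, 10, 10))
  ijk <- round(solve(aff) %*% c(-4, 0, 2, 1))[1:3] + 1
  v[ijk[1], ijk[2], ijk[3]] <- 9
  m <- stat_map(v, aff)
  out2 <- sample_foci(list(m, m, m), fs)
  expect_true(all(out2$values[, "a"] == 9))
  expect_true(all(out2$values[, "b"] == 0))
  expect_equal(out2$summary$mean, c(9, 0))
  # translating map and affine together leaves sampled values unchanged
  aff2 <- aff; aff2[1:3, 4] <- aff2[1:3, 4] + c(10, -6, 4)
  fs2 <- focus_set(fs$label, as.matrix(fs[, c("x", "y", "z")]) +
                     matrix(c(10, -6, 4), 2, 3, byrow = TRUE))
  out3 <- sample_foci(list(stat_map(v, aff2)), fs2)
  expect_equal(unname(out3$values[1, ]), c(9, 0))
  # out-of-bounds focus errors
  expect_error(sample_foci(list(m), focus_set("far", c(500, 0, 0))),
               "field of view")
})

test_that("stat maps round-trip through NIfTI with their affine", {
  sim <- simulate_group_maps(2, dims = c(8, 8, 8), seed = 51)
  m <- sim$groupA[[1]]
  f <- tempfile(fileext = ".nii.gz")
  write_stat_map(m, f)
  back <- read_stat_map(f)
  expect_equal(back$values, m$values, tolerance = 1e-6)
  expect_equal(unname(back$affine), unname(m$affine), tolerance = 1e-5)
})

test_that("focus configurations load from JSON", {
  f <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    list(label = "mSTG_L", mni = c(-55, -14, 8)),
    list(label = "mSTG_R", mni = c(59, 0, 4))), auto_unbox = TRUE), f)
  fs <- read_focus_set(f)
  expect_identical(fs$label, c("mSTG_L", "mSTG_R"))
  expect_equal(fs$x, c(-55, 59))
})
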