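test_that("two-sample maps match the textbook formula oracle", {
  a <- c(3.1, 2.4, 2.9); b <- c(1.0, 1.8, 1.4)
  values <- rbind(matrix(a, 3, 2), matrix(b, 3, 2))
  sm <- second_level_ttest(values, rep(c("TD", "ASD"), each = 3))
  sp <- sqrt(((3 - 1) * var(a) + (3 - 1) * var(b)) / 4)
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(unname(sm$t), rep(t_oracle, 2))
  expect_equal(sm$df, 4)
  # identical groups give t = 0
  same <- rbind(values[1:3, , drop = FALSE], values[1:3, , drop = FALSE])
  expect_equal(unname(second_level_ttest(same,
                                         rep(c("TD", "ASD"), each = 3))$t),
               c(0, 0))
  # 21 vs 21 subjects: df = 40
  v <- matrix(rnorm(42), 42, 1)
  expect_equal(second_level_ttest(v, rep(c("TD", "ASD"), each = 21))$df,
               40)
  expect_error(second_level_ttest(v[1:3, , drop = FALSE],
                                  c("TD", "TD", "ASD")), "2 subjects")
})

test_that("covariate regression maps have df = n - 2 and guard degeneracy", {
  set.seed(5)
  scores <- rnorm(21)
  vals <- matrix(rnorm(21 * 4), 21, 4)
  sm <- covariate_regression(vals, scores)
  expect_equal(sm$df, 19)
  # against lm() as the independent oracle
  fit <- lm(vals[, 2] ~ scores)
  expect_equal(unname(sm$t[2]),
               unname(summary(fit)$coefficients["scores", "t value"]),
               tolerance = 1e-10)
  expect_error(covariate_regression(vals, rep(1, 21)), "degenerate")
  # exactly linear activity gives unbounded t
  lin <- matrix(2 * scores + 1, 21, 1)
  expect_gt(abs(covariate_regression(lin, scores)$t[1]), 1e6)
})

test_that("cluster correction separates sizes around the extent threshold", {
  mask <- mask_spec(c(20, 20, 20), voxel_mm = 2)
  tarr <- array(0, mask$dim)
  tarr[2:8, 2:11, 2] <- 5            # 70-voxel slab
  big <- structure(tarr, df = 40)
  tab <- apply_cluster_correction(big, mask, extent = 67,
                                  voxel_p = 0.005)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$size, 70L)
  expect_true(tab$survives_correction)
  expect_equal(tab$peak_t, 5)
  tarr2 <- array(0, mask$dim)
  tarr2[2:7, 2:12, 2] <- 5           # 66-voxel slab
  tab2 <- apply_cluster_correction(structure(tarr2, df = 40), mask,
                                   extent = 67, voxel_p = 0.005)
  expect_false(any(tab2$survives_correction))
  # null map below threshold: empty table
  null <- structure(array(1, mask$dim), df = 40)
  expect_equal(nrow(apply_cluster_correction(null, mask, extent = 67)),
               0L)
})

test_that("cluster labelling agrees with an independent flood fill", {
  set.seed(7)
  supra <- array(runif(15^3) < 0.3, c(15, 15, 15))
  expect_equal(taskconn:::.max_cluster_size_cpp(supra, dim(supra)),
               naive_max_cluster(supra))
})

test_that("monte carlo thresholds behave across parameters", {
  mask <- mask_spec(c(10, 10, 10), voxel_mm = 2)
  thr <- monte_carlo_cluster_threshold(mask, fwhm_mm = 0,
                                       voxel_p = 0.005, fwe_p = 0.05,
                                       n_iter = 300, seed = 2)
  # independent unsmoothed oracle: same mask, plain R implementation
  set.seed(2)
  zc <- qnorm(0.995)
  oracle_sizes <- replicate(300, {
    v <- array(rnorm(1000), dim = c(10, 10, 10))
    v <- (v - mean(v)) / sd(v)
    naive_max_cluster(v > zc)
  })
  s <- 1L
  while (mean(oracle_sizes >= s) > 0.05) s <- s + 1L
  expect_lte(abs(thr$extent - s), 1L)
  # limit case: fwe_p = 1 accepts any cluster
  thr1 <- monte_carlo_cluster_threshold(mask, fwhm_mm = 0,
                                        voxel_p = 0.005, fwe_p = 1,
                                        n_iter = 50, seed = 3)
  expect_equal(thr1$extent, 1L)
  # monotone in smoothness and in fwe_p
  t_smooth <- monte_carlo_cluster_threshold(mask_spec(c(20, 20, 20)),
                                            fwhm_mm = 6, n_iter = 200,
                                            seed = 4)
  t_rough <- monte_carlo_cluster_threshold(mask_spec(c(20, 20, 20)),
                                           fwhm_mm = 3, n_iter = 200,
                                           seed = 4)
  expect_gte(t_smooth$extent, t_rough$extent)
  t_strict <- monte_carlo_cluster_threshold(mask_spec(c(20, 20, 20)),
                                            fwhm_mm = 6, fwe_p = 0.01,
                                            n_iter = 200, seed = 4)
  expect_gte(t_strict$extent, t_smooth$extent)
  expect_error(monte_carlo_cluster_threshold(mask, voxel_p = 0),
               "voxel_p")
})

test_that("derived extents control the family-wise error on null maps", {
  mask <- mask_spec(c(24, 24, 24), voxel_mm = 2)
  thr <- monte_carlo_cluster_threshold(mask, fwhm_mm = 6,
                                       voxel_p = 0.005, fwe_p = 0.05,
                                       n_iter = 500, seed = 11)
  zc <- qnorm(0.995)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 2
  hits <- local({
    set.seed(99)
    replicate(400, {
      v <- array(rnorm(24^3), mask$dim)
      v <- taskconn:::.smooth3d_cpp(v, mask$dim, rep(sigma, 3))
      v <- (v - mean(v)) / sd(v)
      taskconn:::.max_cluster_size_cpp(v > zc, mask$dim) >= thr$extent
    })
  })
  # binomial 95% CI around 0.05 over 400 null maps
  ci <- qbinom(c(0.025, 0.975), 400, 0.05) / 400
  expect_gte(mean(hits), ci[1] - 1e-9)
  expect_lte(mean(hits), ci[2] + 1e-9)
})

test_that("small volume correction is consistent and more sensitive", {
  mask <- mask_spec(c(30, 30, 30), voxel_mm = 2)
  tarr <- array(0, mask$dim)
  tarr[14:16, 14:16, 14:16] <- 6      # 27-voxel subcortical-sized blob
  map <- structure(tarr, df = 40)
  whole <- small_volume_correct(map, mask, mask, fwhm_mm = 6,
                                n_iter = 200, seed = 5)
  thr_whole <- monte_carlo_cluster_threshold(mask, fwhm_mm = 6,
                                             n_iter = 200, seed = 5)
  ref <- apply_cluster_correction(map, mask, extent = thr_whole$extent)
  expect_equal(whole$survives_correction, ref$survives_correction)
  # a tiny search region has a strictly smaller extent threshold
  roi <- mask_spec(c(30, 30, 30), voxel_mm = 2, shape = "ellipsoid",
                   semiaxes_mm = c(6, 6, 6))
  svc <- small_volume_correct(map, mask, roi, fwhm_mm = 6,
                              n_iter = 200, seed = 5)
  expect_lt(attr(svc, "extent"), thr_whole$extent)
  # the planted blob survives within the small volume but fails the
  # whole-brain extent
  expect_true(any(svc$survives_correction))
  expect_false(any(ref$survives_correction))
  ellip <- mask_spec(c(30, 30, 30), voxel_mm = 2, shape = "ellipsoid",
                     semiaxes_mm = c(20, 20, 20))
  expect_error(small_volume_correct(map, ellip, mask, n_iter = 10),
               "contained")
})

test_that("effect sizes follow the d and f conversion rules", {
  expect_equal(cohens_d_from_t(0, 42), 0)
  expect_equal(cohens_d_from_t(4.5826, 42), 1, tolerance = 1e-4)
  expect_equal(cohens_d_from_t(2.2913, 42), 0.5, tolerance = 1e-4)
  expect_equal(cohens_f_from_t(0, 21), 0)
  expect_equal(cohens_f_from_t(4.5826, 21), 1, tolerance = 1e-4)
  expect_equal(cohens_f_from_t(3, 84), cohens_f_from_t(3, 21) / 2)
  expect_error(cohens_d_from_t(1, 1), "at least 2")
  expect_error(cohens_f_from_t(1, 0), "at least 1")
  # consistency: f = d / sqrt(2) at equal N
  t <- seq(-3, 3, by = 0.5)
  expect_equal(cohens_f_from_t(t, 42),
               cohens_d_from_t(t, 42) / sqrt(2))
})
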