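test_that("design matrix has the documented structure", {
  # two modeled conditions, no catch trials, single run
  spec <- paradigm_spec(n_runs = 1, exemplars_per_condition = 6,
                       catch_per_run = 0)
  sch <- generate_paradigm(spec)
  attr(sch, "tr_s") <- spec$tr_ms / 1000
  attr(sch, "n_vols") <- spec$run_volumes
  des <- build_design(sch)
  # 2 x 2 condition columns + drift + single constant
  n_drift <- sum(grepl("^drift", des$labels))
  expect_equal(ncol(des$X), 2 * 2 + n_drift + 1)
  expect_equal(sum(des$labels == "constant"), 1L)
  # environmental events exist in the schedule but are not modeled
  expect_true("environmental" %in% sch$condition)
  expect_false(any(grepl("environmental", des$labels)))
  expect_true(all(c("mother", "unfamiliar") %in% des$labels))
  expect_false(any(apply(des$X[, des$condition_cols, drop = FALSE], 2,
                         function(x) all(x == 0))))
})

test_that("HRF columns peak ~5 s post-onset and derivatives sum to zero", {
  hrf <- hrf_model()
  k <- hrf_kernel(hrf, 0.1)
  expect_gt(sum(k), 0)
  peak_t <- (which.max(k) - 1) * 0.1
  expect_lt(abs(peak_t - 5), 0.5)
  dk <- hrf_derivative(hrf, 0.1)
  expect_lt(abs(sum(dk) * 0.1), 1e-3)

  # single isolated event: column peak near onset + 5 s
  sch <- data.frame(run = 1, onset = 35.76, duration = 0.956,
                    condition = "mother")
  sch2 <- rbind(sch, data.frame(run = 1, onset = 107.28,
                                duration = 0.956,
                                condition = "unfamiliar"))
  class(sch2) <- c("event_schedule", "data.frame")
  attr(sch2, "tr_s") <- 3.576; attr(sch2, "n_vols") <- 67
  des <- build_design(sch2, baseline = "none")
  col <- des$X[, which(des$labels == "mother")]
  peak_vol <- which.max(col)
  expect_lt(abs((peak_vol - 1) * 3.576 - (35.76 + 5)), 3.576)
})

test_that("a modeled condition with zero events is rejected", {
  sch <- small_schedule(n_runs = 1)
  sch2 <- sch[sch$condition != "mother", ]
  class(sch2) <- c("event_schedule", "data.frame")
  attr(sch2, "tr_s") <- 3.576; attr(sch2, "n_vols") <- 67
  expect_error(build_design(sch2, baseline = "environmental"),
               NA)  # absent entirely is fine: not a modeled condition
  # but an explicitly empty modeled condition errors
  sch3 <- sch
  sch3$condition[sch3$condition == "mother"] <- "unfamiliar"
  class(sch3) <- c("event_schedule", "data.frame")
  # force "mother" modeled by adding zero-event label through schedule
  expect_error(
    build_design(structure(sch3[0, ], class = class(sch),
                           tr_s = 3.576, n_vols = 67)),
    "no modeled conditions|zero events")
})

test_that("noiseless fits recover planted coefficients exactly", {
  sch <- small_schedule()
  tr <- silent_truth()
  tr$activation_beta["pSTS_L", ] <- c(1.0, 0.4, 0)
  bold <- simulate_roi_bold(sch, tr, subject_seed = 1)
  des <- build_design(sch)
  fit <- fit_glm_ar1(bold, des)
  expect_equal(unname(fit$beta["mother", "pSTS_L"]), 1.0,
               tolerance = 1e-8)
  expect_equal(unname(fit$beta["unfamiliar", "pSTS_L"]), 0.4,
               tolerance = 1e-8)
  cc <- compute_contrast(fit, c(mother = 1, unfamiliar = -1))
  expect_equal(unname(cc$value["pSTS_L"]), 0.6, tolerance = 1e-8)
  # baseline contrast is the unfamiliar beta alone
  cb <- compute_contrast(fit, c(unfamiliar = 1))
  expect_equal(unname(cb$value["pSTS_L"]), 0.4, tolerance = 1e-8)
})

test_that("the phi = 0 path reproduces closed-form least squares", {
  sch <- small_schedule(n_runs = 1)
  des <- build_design(sch)
  set.seed(3)
  Y <- matrix(rnorm(67 * 3), 67, 3)
  fit <- fit_glm_ar1(Y, des, phi = 0)
  oracle <- solve(crossprod(des$X), crossprod(des$X, Y))
  expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-10)
  expect_equal(fit$phi, 0)
})

test_that("AR(1) coefficient is recovered from ten-run residuals", {
  sch <- full_schedule()
  tr <- silent_truth()
  tr$noise$phi <- 0.4
  tr$noise$sd <- 1
  bold <- simulate_roi_bold(sch, tr, subject_seed = 8)
  fit <- fit_glm_ar1(bold, build_design(sch))
  expect_lt(abs(fit$phi - 0.4), 0.1)
})

test_that("contrasts are scale-equivariant with invariant t", {
  sch <- small_schedule()
  tr <- default_ground_truth()
  bold <- simulate_roi_bold(sch, tr, subject_seed = 2)
  des <- build_design(sch)
  fit1 <- fit_glm_ar1(bold, des, phi = 0.2)
  scaled <- lapply(bold, function(b) { b$series <- 3 * b$series; b })
  fit2 <- fit_glm_ar1(scaled, des, phi = 0.2)
  c1 <- compute_contrast(fit1, c(mother = 1, unfamiliar = -1))
  c2 <- compute_contrast(fit2, c(mother = 1, unfamiliar = -1))
  expect_equal(c2$value, 3 * c1$value, tolerance = 1e-8)
  expect_equal(c2$t, c1$t, tolerance = 1e-8)
  expect_error(compute_contrast(fit1, c(mother = 0)), "zero")
  expect_error(compute_contrast(fit1, c(nonexistent = 1)), "unknown")
})

test_that("equal coefficients give a zero contrast and zero t", {
  sch <- small_schedule(n_runs = 1)
  tr <- silent_truth()
  tr$activation_beta["AI_L", c("mother", "unfamiliar")] <- 0.7
  tr$noise$sd <- 0.01
  bold <- simulate_roi_bold(sch, tr, subject_seed = 4)
  fit <- fit_glm_ar1(bold, build_design(sch), phi = 0)
  cc <- compute_contrast(fit, c(mother = 1, unfamiliar = -1))
  expect_lt(abs(cc$value["AI_L"]), 0.05)
  expect_lt(abs(cc$t["AI_L"]), 3)
})

test_that("rank-deficient designs are rejected with column names", {
  sch <- small_schedule(n_runs = 1)
  des <- build_design(sch)
  des$X <- cbind(des$X, dup = des$X[, 1])
  des$labels <- c(des$labels, "dup")
  expect_error(fit_glm_ar1(matrix(rnorm(67), 67, 1), des),
               "collinear")
})

test_that("sub-cutoff drift leaks under 1% of its variance into betas", {
  sch <- small_schedule(n_runs = 1)
  des <- build_design(sch)
  # pure slow drift: one cycle per 240 s run (frequency below 1/120 Hz)
  t_s <- (seq_len(67) - 1) * 3.576
  drift <- sin(2 * pi * t_s / 240)
  fit <- fit_glm_ar1(matrix(drift, 67, 1), des, phi = 0)
  cond_beta <- fit$beta[c("mother", "unfamiliar"), 1]
  X <- des$X[, c("mother", "unfamiliar")]
  explained <- var(drop(X %*% cond_beta))
  expect_lt(explained / var(drift), 0.01)
})

test_that("roi extraction averages voxels within the sphere radius", {
  mask <- mask_spec(c(20, 20, 20), voxel_mm = 2)
  map <- array(3.5, mask$dim)
  net <- network_spec("A", x = 2, y = -2, z = 4, cortical = TRUE)
  expect_equal(unname(extract_roi_betas(map, net, mask)), 3.5)
  # voxel membership matches brute-force enumeration on the 2 mm grid
  vox <- taskconn:::sphere_voxels(mask, c(2, -2, 4), 5)
  ctr <- (mask$dim + 1) / 2
  cnt <- 0L
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    mm <- (c(i, j, k) - ctr) * 2
    if (sum((mm - c(2, -2, 4))^2) <= 25) cnt <- cnt + 1L
  }
  expect_equal(length(vox), cnt)
  # center far outside the mask errors
  out <- network_spec("B", x = 100, y = 100, z = 100)
  expect_error(extract_roi_betas(map, out, mask), "intersect")
})
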