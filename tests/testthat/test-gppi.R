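test_that("roi time series extraction handles both input forms", {
  sch <- small_schedule(n_runs = 1)
  net <- default_voice_network()
  tr <- default_ground_truth()
  bold <- simulate_roi_bold(sch, tr, subject_seed = 1)[[1]]
  ts <- extract_roi_timeseries(bold, net)
  expect_equal(dim(ts), c(67L, 16L))
  expect_equal(colnames(ts), net$name)
  # volumetric input: a uniform volume yields identical node series
  mask <- mask_spec(c(12, 12, 12), voxel_mm = 2)
  vol <- structure(list(data = array(rep(seq_len(5), each = 12^3),
                                     c(12, 12, 12, 5)),
                        mask = mask, tr_s = 3.576, run = 1),
                   class = "bold_volume")
  net2 <- network_spec(c("A", "B"), x = c(-4, 4), y = 0, z = 0)
  ts2 <- extract_roi_timeseries(vol, net2)
  expect_equal(ts2[, "A"], seq_len(5))
  expect_equal(ts2[, "A"], ts2[, "B"])
  net3 <- network_spec("far", x = 100, y = 100, z = 100)
  expect_error(extract_roi_timeseries(vol, net3), "far")
})

test_that("deconvolution inverts the hemodynamic convolution", {
  hrf <- hrf_model()
  # zero series stays zero
  z0 <- deconvolve_neural(numeric(67), hrf, 3.576, reg = 1e-3)
  expect_true(all(z0$z == 0))
  expect_error(deconvolve_neural(numeric(67), hrf, 3.576, reg = -1),
               "non-negative")
  # round trip on a noiseless convolved boxcar: < 5% relative error
  sch <- small_schedule(n_runs = 1)
  psi <- taskconn:::condition_boxcar(sch, 1, "mother", 3.576, 67, 16)
  y <- taskconn:::microtime_to_tr(psi, hrf, 3.576, 67)
  dec <- deconvolve_neural(y, hrf, 3.576, reg = 1e-3)
  rel <- sqrt(sum(dec$resid^2) / sum((y - mean(y))^2))
  expect_lt(rel, 0.05)
  # recovered activity tracks the stimulus train at the sampling scale
  psi_tr <- colMeans(matrix(psi, 16))
  expect_gt(cor(dec$z_tr, psi_tr), 0.5)
  # smooth band-limited activity is recovered almost exactly
  t_s <- (seq_len(67) - 1) * 3.576
  slow <- sin(2 * pi * t_s / 60)
  y2 <- taskconn:::microtime_to_tr(rep(slow, each = 16), hrf, 3.576, 67)
  dec2 <- deconvolve_neural(y2, hrf, 3.576, reg = 1e-3)
  keep <- 5:62                        # away from run edges
  expect_gt(cor(dec2$z_tr[keep], slow[keep]), 0.95)
})

test_that("ppi regressors follow the task structure", {
  sch <- small_schedule(n_runs = 1)
  hrf <- hrf_model()
  tr <- silent_truth()
  tr$noise$neural_sd <- 0.35
  bold <- simulate_roi_bold(sch, tr, subject_seed = 3)[[1]]
  sb <- bold$series[, "pSTS_L"]
  nz <- deconvolve_neural(sb, hrf, 3.576, reg = 1e-3)
  regs <- build_ppi_regressors(nz, sch, 1, sb, hrf, 3.576, 67)
  expect_equal(colnames(regs$interaction),
               c("mother", "unfamiliar", "environmental"))
  expect_equal(ncol(regs$interaction), 3L)
  # a condition absent from the schedule gives an all-zero column
  regs2 <- build_ppi_regressors(nz, sch, 1, sb, hrf, 3.576, 67,
                                conditions = c("mother", "absent"))
  expect_true(all(regs2$interaction[, "absent"] == 0))
  expect_true(all(regs2$task[, "absent"] == 0))
  # always-on condition: interaction equals the reconvolved seed
  sch_on <- data.frame(run = 1, onset = (0:66) * 3.576,
                       duration = 3.576, condition = "on")
  class(sch_on) <- c("event_schedule", "data.frame")
  regs3 <- build_ppi_regressors(nz, sch_on, 1, sb, hrf, 3.576, 67,
                                conditions = "on")
  expect_gt(cor(regs3$interaction[, "on"], nz$fitted), 0.99)
})

test_that("gppi fits recover direct seed effects and reject degeneracies", {
  sch <- small_schedule(n_runs = 1)
  hrf <- hrf_model()
  tr <- silent_truth()
  tr$noise$neural_sd <- 0.35
  bold <- simulate_roi_bold(sch, tr, subject_seed = 4)[[1]]
  sb <- bold$series[, "pSTS_L"]
  nz <- deconvolve_neural(sb, hrf, 3.576, reg = 1e-3)
  regs <- build_ppi_regressors(nz, sch, 1, sb, hrf, 3.576, 67)
  # target = copy of seed (plus hairline noise to avoid identity)
  tb <- sb + rnorm(67, sd = 1e-8)
  fit <- fit_gppi(tb, regs)
  expect_equal(unname(fit$seed_beta), 1, tolerance = 1e-4)
  expect_true(all(abs(fit$ppi_beta) < 1e-4))
  expect_error(fit_gppi(sb, regs), "identical")
  expect_error(fit_gppi(rep(1, 67), regs), "zero-variance")
})

test_that("planted coupling is recovered with correct sign and order", {
  sch <- full_schedule()
  hrf <- hrf_model()
  net <- default_voice_network()
  tr <- ground_truth(network = net)
  tr$activation_beta["pSTS_L", ] <- c(0.9, 0.9, 0.3)
  tr$activation_beta["NAc_L", ] <- c(0.6, 0.2, 0)
  tr$modulation["mother", "pSTS_L", "NAc_L"] <- 0.8
  tr$noise <- list(phi = 0, sd = 0, drift_amp = 0, spike_prob = 0,
                   offset = 0,
                   neural_sd = c(pSTS_L = 0.35, NAc_L = 0.05))
  op <- taskconn:::deconv_operator(hrf, 3.576, 67, 1e-3)
  betas <- sapply(1:12, function(s) {
    bold <- simulate_roi_bold(sch, tr, subject_seed = s)
    regs <- lapply(bold, function(b) {
      sb <- b$series[, "pSTS_L"]
      nz <- deconvolve_neural(sb, hrf, 3.576, 1e-3, op = op)
      build_ppi_regressors(nz, sch, b$run, sb, hrf, 3.576, 67)
    })
    tb <- unlist(lapply(bold, function(b) b$series[, "NAc_L"]))
    fit_gppi(tb, regs)$ppi_beta
  })
  expect_true(all(betas["mother", ] > 0))
  expect_true(all(betas["mother", ] > betas["unfamiliar", ]))
  expect_lt(abs(mean(betas["mother", ]) - 0.8), 0.15)
  expect_lt(abs(mean(betas["unfamiliar", ])), 0.1)
})

test_that("network matrices have gPPI structure and null calibration", {
  sch <- small_schedule(n_runs = 2)
  net <- default_voice_network()
  tr <- default_ground_truth()
  bold <- simulate_roi_bold(sch, tr, subject_seed = 5)
  conn <- network_gppi(bold, net, sch)
  m <- conn$mother_gt_unfamiliar
  expect_equal(dim(m), c(16L, 16L))
  expect_true(all(is.na(diag(m))))
  expect_false(isSymmetric(unname(ifelse(is.na(m), 0, m))))
  # contrast of a condition with itself is exactly zero
  same <- network_gppi(bold, net, sch,
                       contrasts = list(zero = c("mother", "mother")))
  expect_true(all(same$zero[!is.na(same$zero)] == 0))
  expect_error(network_gppi(bold, net[1, ], sch), "2 nodes")
})

test_that("null modulation leaves link means within two standard errors", {
  sch <- small_schedule(n_runs = 2)
  net <- default_voice_network()[1:6, ]
  tr <- ground_truth(network = net)    # zero modulation everywhere
  tr$activation_beta[, "mother"] <- 0.5
  mats <- lapply(1:20, function(s) {
    bold <- simulate_roi_bold(sch, tr, subject_seed = 100 + s)
    network_gppi(bold, net, sch)$mother_gt_unfamiliar
  })
  cells <- which(row(mats[[1]]) != col(mats[[1]]))
  vals <- sapply(mats, function(m) m[cells])
  zstat <- rowMeans(vals) / (apply(vals, 1, sd) / sqrt(ncol(vals)))
  # ~95% of null cells within 2 SE; allow sampling slack
  expect_gt(mean(abs(zstat) < 2), 0.85)
})

test_that("link tests apply Benjamini-Hochberg over all links", {
  # hand-computed BH: p = [.001, .01, .02, .8] -> q = [.004, .02, .0267, .8]
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(p.adjust(p, "BH"),
               c(0.004, 0.02, 4 / 3 * 0.02, 0.8), tolerance = 1e-10)
  nodes <- c("A", "B", "C")
  mk <- function(vals) {
    m <- matrix(NA_real_, 3, 3, dimnames = list(nodes, nodes))
    m[row(m) != col(m)] <- vals
    m
  }
  set.seed(8)
  # planted group difference in one cell, none elsewhere
  g <- rep(c("TD", "ASD"), each = 10)
  mats <- lapply(1:20, function(i) {
    v <- rnorm(6, sd = 0.1)
    if (g[i] == "TD") v[1] <- v[1] + 2
    mk(v)
  })
  lt <- univariate_link_tests(mats, groups = g)
  expect_equal(nrow(lt), 6L)
  expect_true(lt$significant[1])
  expect_equal(sum(lt$significant), 1L)
  expect_equal(lt$q, p.adjust(lt$p, "BH"))
  # identical groups: nothing significant
  mats2 <- rep(mats[1:10], 2)
  lt2 <- univariate_link_tests(mats2, groups = g)
  expect_false(any(lt2$significant))
  # score mode returns Pearson correlations
  sc <- rnorm(20)
  lt3 <- univariate_link_tests(mats, scores = sc)
  v1 <- sapply(mats, function(m) m["B", "A"])
  expect_equal(lt3$statistic[1], cor(v1, sc))
})
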