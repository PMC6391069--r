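make_conn_set <- function(vals, nodes) {
  m <- matrix(NA_real_, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  m[row(m) != col(m)] <- vals
  structure(list(c1 = m, c2 = m * 2), class = "connectivity_set")
}

test_that("feature assembly vectorizes off-diagonals deterministically", {
  nodes <- sprintf("n%02d", 1:16)
  subs <- lapply(1:5, function(i) make_conn_set(rnorm(240), nodes))
  X1 <- assemble_features(subs, "c1")
  expect_equal(dim(X1), c(5L, 240L))
  X2 <- assemble_features(subs, c("c1", "c2"))
  expect_equal(ncol(X2), 480L)
  expect_equal(unname(X2[, 241:480]), unname(2 * X2[, 1:240]))
  # vectorize / unvectorize round trip
  m <- subs[[1]]$c1
  v <- vectorize_links(m, "c1")
  expect_equal(unvectorize_links(unname(v), nodes), m)
  expect_error(assemble_features(subs, "missing"), "missing")
})

test_that("svc recovers separable classes and stays at chance on noise", {
  set.seed(1)
  n <- 24
  g <- rep(c("TD", "ASD"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[g == "TD", 1:3] <- X[g == "TD", 1:3] + 4
  res <- svc_cross_validate(X, g, C = 1, k = 4, repeats = 10, seed = 2)
  expect_gte(res$accuracy, 0.95)
  expect_equal(res$settings$C, 1)
  expect_equal(res$settings$k, 4)
  expect_equal(res$settings$repeats, 10)
  # pure noise: near chance
  Xn <- matrix(rnorm(n * 10), n, 10)
  resn <- svc_cross_validate(Xn, g, repeats = 25, seed = 3)
  expect_gte(resn$accuracy, 0.3)
  expect_lte(resn$accuracy, 0.7)
  expect_error(svc_cross_validate(X[c(1:3, 13:14), ],
                                  g[c(1:3, 13:14)], k = 4),
               "at least k")
  expect_error(svc_cross_validate(X[1:5, ], g[1:5], k = 4),
               "two classes")
})

test_that("classification permutation p has the (1+B) floor", {
  set.seed(4)
  g <- rep(c("TD", "ASD"), each = 10)
  X <- matrix(rnorm(20 * 4), 20, 4)
  X[g == "TD", ] <- X[g == "TD", ] + 10    # perfectly separable
  obs <- svc_cross_validate(X, g, repeats = 3, seed = 1)
  pt <- permutation_test_classification(X, g, obs, n_perm = 39, seed = 2)
  expect_equal(pt$p, 1 / 40)
  expect_gte(min(pt$p), 1 / (39 + 1))
  # observed at or below the permutation distribution: large p
  Xn <- matrix(rnorm(20 * 4), 20, 4)
  obsn <- svc_cross_validate(Xn, g, repeats = 3, seed = 1)
  obsn$accuracy <- 0.1
  ptn <- permutation_test_classification(Xn, g, obsn, n_perm = 19,
                                         seed = 2)
  expect_gt(ptn$p, 0.5)
  expect_error(permutation_test_classification(Xn, g, obsn, n_perm = 0),
               "at least 1")
})

test_that("balanced folds pass the fold-wise ANOVA criterion", {
  set.seed(5)
  y <- rnorm(24)
  X <- matrix(rnorm(24 * 3), 24, 3)
  f <- balanced_fold_assignment(y, X, k = 4, seed = 7)
  expect_equal(sort(unique(f)), 1:4)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  expect_gt(taskconn:::anova_p(y, f), 0.05)
  for (j in 1:3) expect_gt(taskconn:::anova_p(X[, j], f), 0.05)
  expect_identical(balanced_fold_assignment(y, X, k = 4, seed = 7), f)
  expect_error(balanced_fold_assignment(rnorm(5), k = 4), "per fold")
  # pathological balance demand falls back with a warning
  ybad <- c(rep(0, 12), rep(100, 12))
  expect_warning(
    balanced_fold_assignment(ybad, matrix(ybad, ncol = 1), k = 4,
                             alpha = 0.9999, max_tries = 5, seed = 1),
    "no balanced partition")
})

test_that("cross-validated regression predicts linear signal", {
  set.seed(6)
  X <- matrix(rnorm(24 * 2), 24, 2)
  y <- 3 * X[, 1] + 1
  f <- balanced_fold_assignment(y, X, k = 4, seed = 2)
  rr <- cv_regression_predict(X, y, f, model = "ols")
  expect_gte(rr$r, 0.999)
  # svr path on the same data
  rs <- cv_regression_predict(X, y, f, model = "svr")
  expect_gte(rs$r, 0.95)
  # OLS degeneracy guard
  Xw <- matrix(rnorm(24 * 30), 24, 30)
  expect_error(cv_regression_predict(Xw, y, f, model = "ols"),
               "degenerate")
  # pure-noise features: near-zero mean r over repetitions
  rn <- replicate(40, {
    Xn <- matrix(rnorm(24 * 3), 24, 3)
    yn <- rnorm(24)
    cv_regression_predict(Xn, yn, sample(rep_len(1:4, 24)),
                          model = "ols")$r
  })
  expect_lt(abs(mean(rn)), 0.15)
})

test_that("regression permutation test grades association strength", {
  set.seed(7)
  X <- matrix(rnorm(24 * 2), 24, 2)
  y <- 2 * X[, 1] + rnorm(24, sd = 0.3)
  f <- balanced_fold_assignment(y, X, k = 4, seed = 3)
  obs <- cv_regression_predict(X, y, f, model = "ols")
  pt <- permutation_test_regression(X, y, f, obs, n_surrogates = 99,
                                    seed = 4)
  expect_lte(pt$p, 0.01)
  # an anti-predictive observation is beaten by almost all surrogates
  obs_bad <- obs
  obs_bad$r <- -1
  pt_bad <- permutation_test_regression(X, y, f, obs_bad,
                                        n_surrogates = 49, seed = 5)
  expect_gt(pt_bad$p, 0.9)
})

test_that("standardization never uses held-out subjects", {
  X <- matrix(rnorm(20 * 3), 20, 3)
  zs1 <- taskconn:::zscore_train_test(X[1:15, ], X[16:20, ])
  # corrupting the held-out rows must not change the training transform
  X2 <- X
  X2[16:20, ] <- X2[16:20, ] + 1000
  zs2 <- taskconn:::zscore_train_test(X2[1:15, ], X2[16:20, ])
  expect_equal(zs1$train, zs2$train)
  expect_equal(zs2$test, zs1$test + 1000 / rep(apply(X[1:15, ], 2, sd),
                                               each = 5))
})

test_that("penalized glm matches svc on planted effects and finds sparsity", {
  set.seed(9)
  n <- 32
  g <- factor(rep(c("TD", "ASD"), each = n / 2))
  X <- matrix(rnorm(n * 60), n, 60)
  informative <- c(3, 17, 29, 41, 55)
  X[g == "TD", informative] <- X[g == "TD", informative] + 3
  colnames(X) <- sprintf("f%02d", 1:60)
  glm_res <- penalized_glm_confirm(X, g, k = 4, repeats = 5, seed = 2)
  svc_res <- svc_cross_validate(X, g, k = 4, repeats = 5, seed = 2)
  expect_gte(glm_res$accuracy, 0.9)
  expect_gte(svc_res$accuracy, 0.9)
  recall <- mean(sprintf("f%02d", informative) %in% glm_res$nonzero)
  expect_gte(recall, 0.6)
  # regression flavour
  yq <- drop(X[, informative] %*% rep(0.5, 5)) + rnorm(n, sd = 0.5)
  rr <- penalized_glm_confirm(X, yq, k = 4, seed = 3)
  expect_gte(rr$r, 0.7)
  expect_error(penalized_glm_confirm(matrix(0, n, 4), g),
               "zero variance")
})
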