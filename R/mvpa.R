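#' Assemble a subjects-by-features matrix from connectivity or ROI data
#'
#' Connectivity matrices are vectorized over off-diagonal cells
#' (`n * (n - 1)` ordered-pair features per contrast, deterministic
#' column-major order) and concatenated across the requested contrasts.
#' A plain subjects x variables table (e.g. ROI contrast betas) is
#' passed through with its column names.
#'
#' @param source either a list of per-subject `connectivity_set`s (from
#'   [network_gppi()]) or a numeric subjects x variables matrix.
#' @param contrasts contrast names to extract from each
#'   `connectivity_set`.
#' @return A `feature_matrix`: numeric matrix with feature-id column
#'   names (`contrast:seed->target`).
#' @export
assemble_features <- function(source, contrasts = NULL) {
  if (is.matrix(source) || is.data.frame(source)) {
    X <- as.matrix(source)
    if (anyNA(X)) stop("feature matrix contains missing values")
    class(X) <- c("feature_matrix", class(X))
    return(X)
  }
  stopifnot(is.list(source), length(source) >= 1)
  if (is.null(contrasts))
    contrasts <- setdiff(names(source[[1]]), ".betas")
  missing <- which(vapply(source, function(s)
    !all(contrasts %in% names(s)), logical(1)))
  if (length(missing))
    stop(sprintf("subjects missing requested contrasts: %s",
                 paste(missing, collapse = ", ")))
  rows <- lapply(source, function(s) {
    unlist(lapply(contrasts, function(ct) vectorize_links(s[[ct]], ct)))
  })
  X <- do.call(rbind, rows)
  class(X) <- c("feature_matrix", class(X))
  X
}

#' Vectorize and restore off-diagonal cells of a connectivity matrix
#'
#' @param m square seed x target matrix with node dimnames.
#' @param prefix feature-name prefix (the contrast label).
#' @return `vectorize_links`: named vector of `n * (n - 1)` off-diagonal
#'   values; `unvectorize_links`: the matrix restored with an NA
#'   diagonal.
#' @export
vectorize_links <- function(m, prefix = "link") {
  nodes <- rownames(m)
  off <- which(row(m) != col(m))
  idx <- arrayInd(off, dim(m))
  v <- m[off]
  names(v) <- sprintf("%s:%s->%s", prefix, nodes[idx[, 1]],
                      nodes[idx[, 2]])
  v
}

#' @rdname vectorize_links
#' @param v vector produced by [vectorize_links()].
#' @param nodes node names of the original matrix.
#' @export
unvectorize_links <- function(v, nodes) {
  n <- length(nodes)
  m <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  m[which(row(m) != col(m))] <- v
  m
}

zscore_train_test <- function(train, test) {
  mu <- colMeans(train)
  sdev <- apply(train, 2, sd)
  sdev[sdev == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdev, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdev, "/"))
}

# Stratified k-fold partition: both classes represented in every fold.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lev in unique(labels)) {
    i <- sample(which(labels == lev))
    fold[i] <- rep_len(sample(k), length(i))
  }
  fold
}

#' Cross-validated linear support vector classification
#'
#' Repeated stratified k-fold cross-validation of a linear soft-margin
#' SVM: per repeat the data are randomly partitioned into k folds
#' (stratified so both classes appear in every training set), features
#' are z-scored using training-fold statistics only, a linear SVM with
#' cost `C` is trained on k-1 folds and tested on the held-out fold, and
#' fold accuracies are averaged; the reported accuracy is the mean over
#' repeats.
#'
#' @param X a [assemble_features()] matrix (subjects x features).
#' @param labels two-level class labels.
#' @param C SVM cost parameter.
#' @param k number of folds.
#' @param repeats number of random re-partitions.
#' @param seed integer seed.
#' @return A `classification_result`: list with `accuracy` (mean over
#'   repeats), `per_repeat`, and `settings`.
#' @export
svc_cross_validate <- function(X, labels, C = 1, k = 4, repeats = 100,
                               seed = 1L) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("exactly two classes required")
  if (min(table(labels)) < k)
    stop("each class needs at least k subjects")
  per_repeat <- with_seed(seed, {
    vapply(seq_len(repeats), function(rep) {
      fold <- stratified_folds(labels, k)
      accs <- vapply(seq_len(k), function(f) {
        tr <- fold != f; te <- !tr
        zs <- zscore_train_test(X[tr, , drop = FALSE],
                                X[te, , drop = FALSE])
        fit <- e1071::svm(zs$train, labels[tr], kernel = "linear",
                          cost = C, scale = FALSE)
        mean(predict(fit, zs$test) == labels[te])
      }, numeric(1))
      mean(accs)
    }, numeric(1))
  })
  structure(list(accuracy = mean(per_repeat), per_repeat = per_repeat,
                 settings = list(C = C, k = k, repeats = repeats,
                                 seed = seed, method = "svc")),
            class = "classification_result")
}

#' Permutation test for classification accuracy
#'
#' Class labels are randomly permuted `n_perm` times and the full
#' cross-validation procedure is repeated with the observed settings;
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)`, floored at
#' `1 / (n_perm + 1)`.
#'
#' @param X,labels as in [svc_cross_validate()].
#' @param observed a `classification_result` computed on the true
#'   labels.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return The observed result with elements `p` and `perm_accuracies`
#'   added.
#' @export
permutation_test_classification <- function(X, labels, observed,
                                            n_perm = 1000, seed = 1L) {
  stopifnot(inherits(observed, "classification_result"))
  if (n_perm < 1) stop("`n_perm` must be at least 1")
  s <- observed$settings
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pl <- sample(labels)
      svc_cross_validate(X, pl, C = s$C, k = s$k, repeats = s$repeats,
                         seed = derive_seed(seed, b))$accuracy
    }, numeric(1))
  })
  observed$p <- (1 + sum(perm >= observed$accuracy)) / (1 + n_perm)
  observed$perm_accuracies <- perm
  observed
}

#' Balanced fold assignment for cross-validated regression
#'
#' Randomly assigns subjects to k near-equal folds, repeating until
#' one-way ANOVAs of the dependent variable and of every independent
#' variable across folds are all non-significant (p > alpha), so that
#' variable distributions are balanced across folds. If `max_tries` is
#' exhausted the partition maximizing the minimum ANOVA p is returned
#' with a warning.
#'
#' @param y dependent variable (scores).
#' @param X optional feature matrix whose columns must also balance.
#' @param k number of folds.
#' @param alpha ANOVA significance level for rejecting a partition.
#' @param max_tries maximum partitions tried.
#' @param seed integer seed.
#' @return Integer fold labels in `1:k` (deterministic given `seed`),
#'   with attribute `min_anova_p`.
#' @export
balanced_fold_assignment <- function(y, X = NULL, k = 4, alpha = 0.05,
                                     max_tries = 10000, seed = 1L) {
  n <- length(y)
  if (n < 2 * k) stop("need at least 2 subjects per fold")
  with_seed(seed, {
    best <- NULL; best_p <- -Inf
    for (i in seq_len(max_tries)) {
      fold <- sample(rep_len(sample(k), n))
      ps <- anova_p(y, fold)
      if (!is.null(X))
        ps <- c(ps, apply(as.matrix(X), 2, anova_p, fold = fold))
      mp <- min(ps)
      if (mp > best_p) { best_p <- mp; best <- fold }
      if (mp > alpha) break
    }
    if (best_p <= alpha)
      warning(sprintf(
        "no balanced partition found in %d tries; using best (min ANOVA p = %.3g)",
        max_tries, best_p))
    structure(best, min_anova_p = best_p)
  })
}

anova_p <- function(v, fold) {
  if (var(v) == 0) return(1)
  summary(stats::aov(v ~ factor(fold)))[[1]][["Pr(>F)"]][1]
}

#' Cross-validated regression prediction of behavior scores
#'
#' For each fold, a linear model (ordinary least squares for
#' low-dimensional features, linear epsilon-SVR for high-dimensional
#' ones) is trained on the remaining folds (features z-scored with
#' training statistics) and used to predict the held-out subjects.
#' Out-of-fold predictions are concatenated and summarized as
#' `r(predicted, observed)`, the Pearson correlation between predicted
#' and observed scores.
#'
#' @param X feature matrix (subjects x features).
#' @param y observed scores.
#' @param folds fold labels (e.g. from [balanced_fold_assignment()]).
#' @param model `"ols"` or `"svr"`; OLS requires fewer features than the
#'   smallest training fold.
#' @param C,epsilon linear SVR cost and epsilon-tube parameters.
#' @return A `regression_result`: list with `r` (r(predicted,
#'   observed)), `predicted`, `observed`, `folds`, `settings`.
#' @export
cv_regression_predict <- function(X, y, folds, model = c("ols", "svr"),
                                  C = 1, epsilon = 0.1) {
  model <- match.arg(model)
  X <- as.matrix(X)
  pred <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (model == "ols" && ncol(X) >= sum(tr))
      stop(paste("OLS is degenerate: as many features as training",
                 "subjects; use model = \"svr\" or a penalized model"))
    zs <- zscore_train_test(X[tr, , drop = FALSE],
                            X[!tr, , drop = FALSE])
    if (model == "ols") {
      dtr <- data.frame(y = y[tr], zs$train)
      fit <- lm(y ~ ., data = dtr)
      pred[!tr] <- predict(fit, data.frame(zs$test))
    } else {
      # constant training scores leave every point inside the epsilon
      # tube (no support vectors); predict the training mean then
      pred[!tr] <- tryCatch({
        fit <- e1071::svm(zs$train, y[tr], kernel = "linear", cost = C,
                          epsilon = epsilon, scale = FALSE,
                          type = "eps-regression")
        predict(fit, zs$test)
      }, error = function(e) rep(mean(y[tr]), sum(!tr)))
    }
  }
  r <- if (sd(pred) == 0) 0 else cor(pred, y)
  structure(list(r = r, predicted = pred, observed = y, folds = folds,
                 settings = list(model = model, C = C,
                                 epsilon = epsilon)),
            class = "regression_result")
}

#' Permutation test for cross-validated regression
#'
#' Surrogate datasets are generated under the null hypothesis of no
#' association by permuting the scores against the features; the full
#' cross-validated prediction is recomputed for each surrogate and
#' `p = (1 + #{surrogate r >= observed r}) / (1 + n_surrogates)`.
#'
#' @param X,y,folds as in [cv_regression_predict()].
#' @param observed a `regression_result` on the true pairing.
#' @param n_surrogates number of surrogate datasets.
#' @param seed integer seed.
#' @return The observed result with `p` and `perm_r` added.
#' @export
permutation_test_regression <- function(X, y, folds, observed,
                                        n_surrogates = 1000, seed = 1L) {
  stopifnot(inherits(observed, "regression_result"))
  if (n_surrogates < 1) stop("`n_surrogates` must be at least 1")
  s <- observed$settings
  perm <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(b) {
      cv_regression_predict(X, sample(y), folds, model = s$model,
                            C = s$C, epsilon = s$epsilon)$r
    }, numeric(1))
  })
  observed$p <- (1 + sum(perm >= observed$r)) / (1 + n_surrogates)
  observed$perm_r <- perm
  observed
}

#' Penalized-GLM confirmatory classification or regression
#'
#' An elastic-net-penalized generalized linear model (logistic for class
#' labels, Gaussian for scores) with penalty strength chosen by inner
#' cross-validation on the training folds, evaluated under the same
#' outer cross-validation scheme as the primary SVM analyses.
#'
#' @param X feature matrix (subjects x features).
#' @param y two-level labels (classification) or numeric scores
#'   (regression).
#' @param k outer folds.
#' @param repeats outer repeats (classification only).
#' @param alpha elastic-net mixing parameter.
#' @param inner_nfolds folds of the inner penalty-selection CV.
#' @param seed integer seed.
#' @return A `classification_result` or `regression_result`; the
#'   element `nonzero` names features with non-zero coefficients in a
#'   final whole-sample fit at the inner-CV-selected penalty.
#' @export
penalized_glm_confirm <- function(X, y, k = 4, repeats = 10,
                                  alpha = 0.5, inner_nfolds = 3,
                                  seed = 1L) {
  X <- as.matrix(X)
  classify <- is.factor(y) || is.character(y)
  family <- if (classify) "binomial" else "gaussian"
  if (all(apply(X, 2, sd) == 0))
    stop("degenerate penalty path: all features have zero variance")
  fit_and_predict <- function(Xtr, ytr, Xte) {
    # small-fold warnings from the inner CV are expected at these n
    cvfit <- suppressWarnings(
      glmnet::cv.glmnet(Xtr, ytr, family = family, alpha = alpha,
                        nfolds = inner_nfolds))
    predict(cvfit, Xte, s = "lambda.min",
            type = if (classify) "class" else "response")
  }
  out <- with_seed(seed, {
    if (classify) {
      y <- factor(y)
      per_repeat <- vapply(seq_len(repeats), function(rep) {
        fold <- stratified_folds(y, k)
        mean(vapply(seq_len(k), function(f) {
          tr <- fold != f
          zs <- zscore_train_test(X[tr, , drop = FALSE],
                                  X[!tr, , drop = FALSE])
          mean(fit_and_predict(zs$train, y[tr], zs$test) ==
                 as.character(y[!tr]))
        }, numeric(1)))
      }, numeric(1))
      structure(list(accuracy = mean(per_repeat),
                     per_repeat = per_repeat,
                     settings = list(alpha = alpha, k = k,
                                     repeats = repeats, seed = seed,
                                     method = "glmnet")),
                class = "classification_result")
    } else {
      fold <- sample(rep_len(sample(k), length(y)))
      pred <- numeric(length(y))
      for (f in seq_len(k)) {
        tr <- fold != f
        zs <- zscore_train_test(X[tr, , drop = FALSE],
                                X[!tr, , drop = FALSE])
        pred[!tr] <- fit_and_predict(zs$train, y[tr], zs$test)
      }
      structure(list(r = if (sd(pred) == 0) 0 else cor(pred, y),
                     predicted = pred, observed = y, folds = fold,
                     settings = list(alpha = alpha, k = k, seed = seed,
                                     model = "glmnet")),
                class = "regression_result")
    }
  })
  # whole-sample sparsity pattern at the selected penalty
  out$nonzero <- with_seed(derive_seed(seed, 1), {
    z <- scale(X); z[, apply(X, 2, sd) == 0] <- 0
    cvfit <- suppressWarnings(
      glmnet::cv.glmnet(z, if (classify) factor(y) else y,
                        family = family, alpha = alpha,
                        nfolds = inner_nfolds))
    cf <- as.matrix(coef(cvfit, s = "lambda.min"))[-1, , drop = FALSE]
    rownames(cf)[cf[, 1] != 0]
  })
  out
}
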