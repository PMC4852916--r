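#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds, stratified by class so fold
#' sizes differ by at most one within each class. Deterministic given
#' `seed`; the caller's RNG stream is left untouched.
#'
#' @param y binary 0/1 response vector.
#' @param k number of folds (`>= 2`).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:k`, one per sample.
#' @export
make_folds <- function(y, k, seed = 1) {
  n <- length(y)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (k > n) stop("`k` cannot exceed the number of samples", call. = FALSE)
  folds <- integer(n)
  with_local_seed(seed, {
    if (min(table(y)) < k) {
      warning("a class has fewer members than folds; using plain splitting",
              call. = FALSE)
      folds[] <- sample(rep_len(seq_len(k), n))
    } else {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
  })
  folds
}

#' Classification accuracy
#'
#' Fraction of exact label matches.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return a number in `[0, 1]`.
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("length mismatch", call. = FALSE)
  mean(y_true == y_pred)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' sample scores higher than a randomly chosen negative one, with ties
#' contributing 1/2.
#'
#' @param y_true binary 0/1 labels.
#' @param scores numeric classifier scores (higher means more positive).
#' @return a number in `[0, 1]`.
#' @export
auc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    stop("length mismatch", call. = FALSE)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes are required to compute AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# mean binomial deviance of predicted probabilities
binomial_deviance <- function(y, prob) {
  prob <- pmin(pmax(prob, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(prob) + (1 - y) * log(1 - prob))
}

#' Two-dimensional (lambda, alpha) cross-validation
#'
#' Tunes the penalty by K-fold cross-validation over a grid of `lambda`
#' values (log-spaced from `lambda_max` down, computed per `alpha` on the
#' full training data) and a grid of `alpha` mixing weights. Within each
#' training fold the full warm-started lambda path is refit from scratch
#' (standardization included, so no information leaks from the held-out
#' fold), and the held-out samples are scored by classification accuracy at
#' the 0.5 cutoff (or binomial deviance).
#'
#' The selected cell maximizes mean accuracy (minimizes deviance); ties are
#' broken towards larger `lambda` (the sparser model), then larger `alpha`.
#' The `"one_se"` rule instead takes the sparsest cell whose score is within
#' one standard error of the best.
#'
#' @inheritParams hlr_path
#' @param alphas numeric vector of mixing weights; defaults to
#'   `c(0.1, 0.3, 0.5, 0.7, 0.9, 1)` for the two-parameter families (the
#'   `alpha = 1` endpoint is the family's pure-sparsity boundary, where the
#'   optimum sits when grouping is weak) and to the family's fixed value
#'   otherwise.
#' @param k number of folds.
#' @param seed integer seed controlling the fold assignment.
#' @param folds optional externally supplied fold assignment (integer vector
#'   in `1:k`, one entry per sample); overrides `k` and `seed`.
#' @param metric `"accuracy"` or `"deviance"`.
#' @param rule `"min"` (best mean score) or `"one_se"`.
#' @param refit refit on the full data at the selected cell (default `TRUE`).
#' @return an object of class `"hlr_cv"`: matrices `lambda`, `cv_score`,
#'   `cv_se` (rows index the lambda grid, columns the alphas), the selected
#'   `best_lambda`, `best_alpha`, `best_score`, and (if `refit`) the fitted
#'   `"hlr_model"` in `$fit`.
#' @examples
#' set.seed(7)
#' X <- matrix(rnorm(80 * 15), 80, 15)
#' y <- rbinom(80, 1, plogis(2 * X[, 1] - 2 * X[, 2]))
#' cv <- cv_hlr(X, y, family = "l1", k = 5, nlambda = 10, seed = 1)
#' cv$best_lambda
#' @export
cv_hlr <- function(X, y, family = "hlr", alphas = NULL, lambda = NULL,
                   nlambda = 30, lambda_min_ratio = 0.01, k = 10, seed = 1,
                   metric = c("accuracy", "deviance"),
                   rule = c("min", "one_se"), intercept = TRUE,
                   standardize = TRUE, tol = 1e-4, max_outer = 100,
                   max_inner = 100, refit = TRUE, folds = NULL,
                   update_rule = c("exact", "composed")) {
  metric <- match.arg(metric)
  update_rule <- match.arg(update_rule)
  rule <- match.arg(rule)
  family <- method_family(family)
  X <- as.matrix(X)
  check_xy(X, y, binary = TRUE)
  if (is.null(alphas)) {
    alphas <- if (family %in% c("hlr", "en")) c(0.1, 0.3, 0.5, 0.7, 0.9, 1)
              else switch(family, l1 = 1, half = 1, l2 = 0)
  }
  na <- length(alphas)
  # per-alpha lambda grids from the full training data
  lambda_grid <- matrix(0, nlambda, na)
  if (is.null(lambda)) {
    for (a in seq_len(na)) {
      spec0 <- penalty_spec(family, lambda = 1, alpha = alphas[a])
      std <- standardize_x(X, intercept, standardize)
      lmax <- lambda_max_value(std$X, y, spec0$alpha, spec0$operator,
                               gaussian = FALSE, intercept = intercept,
                               composed = update_rule == "composed")
      lambda_grid[, a] <- build_lambda_seq(lmax, nlambda, lambda_min_ratio)
    }
  } else {
    if (anyDuplicated(lambda)) {
      warning("duplicated lambda values removed", call. = FALSE)
      lambda <- unique(lambda)
    }
    lambda <- sort(lambda, decreasing = TRUE)
    nlambda <- length(lambda)
    lambda_grid <- matrix(lambda, nlambda, na)
  }

  if (is.null(folds)) folds <- make_folds(y, k, seed)
  else if (length(folds) != length(y))
    stop("`folds` must have one entry per sample", call. = FALSE)
  nfold <- max(folds)
  score <- array(NA_real_, c(nlambda, na, nfold))
  devn <- array(NA_real_, c(nlambda, na, nfold))
  for (f in seq_len(nfold)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
      warning(sprintf("fold %d has a single class; skipped", f),
              call. = FALSE)
      next
    }
    for (a in seq_len(na)) {
      path <- hlr_path(X[tr, , drop = FALSE], y[tr], family = family,
                       alpha = alphas[a], lambda = lambda_grid[, a],
                       intercept = intercept, standardize = standardize,
                       tol = tol, max_outer = max_outer,
                       max_inner = max_inner, update_rule = update_rule)
      eta <- sweep(X[!tr, , drop = FALSE] %*% path$beta, 2, path$intercept,
                   "+")
      prob <- logistic_prob(eta)
      devn[, a, f] <- apply(prob, 2,
                            function(pc) binomial_deviance(y[!tr], pc))
      score[, a, f] <- if (metric == "accuracy") {
        colMeans((prob >= 0.5) == y[!tr])
      } else {
        devn[, a, f]
      }
    }
  }
  if (all(is.na(score))) stop("all folds failed", call. = FALSE)
  cv_score <- apply(score, c(1, 2), mean, na.rm = TRUE)
  cv_dev <- apply(devn, c(1, 2), mean, na.rm = TRUE)
  cv_se <- apply(score, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    sd(v) / sqrt(length(v))
  })

  maximize <- metric == "accuracy"
  sc <- if (maximize) cv_score else -cv_score
  best_val <- max(sc)
  eligible <- which(sc >= best_val - 1e-12, arr.ind = TRUE)
  if (rule == "one_se") {
    i_best <- eligible[1, ]
    se_best <- cv_se[i_best[1], i_best[2]]
    if (is.finite(se_best))
      eligible <- which(sc >= best_val - se_best, arr.ind = TRUE)
  }
  # ties -> larger lambda (sparser model), then smaller alpha (favouring the
  # grouped solution among equally accurate cells)
  lam_vals <- lambda_grid[eligible]
  alp_vals <- alphas[eligible[, 2]]
  ord <- order(-lam_vals, alp_vals)
  pick <- eligible[ord[1], , drop = TRUE]
  best_lambda <- lambda_grid[pick[1], pick[2]]
  best_alpha <- alphas[pick[2]]

  fit <- NULL
  if (refit) {
    fit <- hlr_fit(X, y, penalty_spec(family, lambda = best_lambda,
                                      alpha = best_alpha),
                   intercept = intercept, standardize = standardize,
                   tol = tol, max_outer = max_outer, max_inner = max_inner,
                   update_rule = update_rule)
  }
  structure(
    list(family = family, lambda = lambda_grid, alphas = alphas,
         cv_score = cv_score, cv_se = cv_se, metric = metric, rule = rule,
         k = nfold, seed = seed, best_lambda = best_lambda,
         best_alpha = best_alpha,
         best_score = cv_score[pick[1], pick[2]], fit = fit),
    class = "hlr_cv")
}

#' @export
print.hlr_cv <- function(x, ...) {
  cat(sprintf(
    "<hlr_cv> family=%s, %d-fold CV over %d lambda x %d alpha (%s, rule=%s)\n",
    x$family, x$k, nrow(x$lambda), length(x$alphas), x$metric, x$rule))
  cat(sprintf("  best: lambda=%.5g alpha=%.2g (%s %.4f)\n", x$best_lambda,
              x$best_alpha, x$metric, x$best_score))
  invisible(x)
}

#' Export a CV surface as TSV
#'
#' Writes one row per (lambda, alpha) cell with the mean score and its
#' standard error.
#'
#' @param cv an `"hlr_cv"` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_cv_surface <- function(cv, file) {
  df <- expand.grid(row = seq_len(nrow(cv$lambda)),
                    alpha = cv$alphas, KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(lambda = cv$lambda[cbind(df$row, match(df$alpha, cv$alphas))],
                   alpha = df$alpha,
                   mean_score = as.vector(cv$cv_score),
                   se = as.vector(cv$cv_se))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
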