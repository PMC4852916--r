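#' Overflow-safe logistic function
#'
#' Elementwise \eqn{e^\eta / (1 + e^\eta)}, clipped away from 0 and 1 so that
#' downstream log-likelihoods and IRLS weights stay finite.
#'
#' @param eta numeric vector of linear predictor values.
#' @param eps clipping bound; probabilities are restricted to
#'   `[eps, 1 - eps]`.
#' @return numeric vector of probabilities.
#' @export
logistic_prob <- function(eta, eps = 1e-10) {
  if (anyNA(eta)) stop("`eta` must be finite", call. = FALSE)
  pmin(pmax(plogis(eta), eps), 1 - eps)
}

#' Negative log-likelihood of a fitted model
#'
#' \deqn{L(\beta) = -\sum_i \{ y_i \log f(\eta_i) + (1-y_i)\log(1-f(\eta_i))\}}
#' with \eqn{\eta = \beta_0 + X\beta}. The penalized objective the solver
#' targets is this plus the penalty value; see [hlr_objective()].
#'
#' @param X numeric matrix (samples x features), original scale.
#' @param y binary 0/1 response vector.
#' @param model an `"hlr_model"` fit, or a coefficient vector (then
#'   `intercept` supplies the offset).
#' @param intercept intercept value when `model` is a plain vector.
#' @return the negative log-likelihood (a single number).
#' @export
neg_log_likelihood <- function(X, y, model, intercept = 0) {
  X <- as.matrix(X)
  if (inherits(model, "hlr_model")) {
    beta <- model$beta
    intercept <- model$intercept
  } else beta <- model
  if (ncol(X) != length(beta))
    stop("ncol(X) must equal length(beta)", call. = FALSE)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  pr <- logistic_prob(drop(intercept + X %*% beta))
  -sum(y * log(pr) + (1 - y) * log(1 - pr))
}

#' Penalized objective of a fitted model
#'
#' Negative log-likelihood plus
#' \eqn{\lambda(\alpha\|\beta\|_{1/2} + (1-\alpha)\|\beta\|_2^2)}
#' (with L1 norms for the soft-threshold families).
#'
#' @inheritParams neg_log_likelihood
#' @param spec penalty used when `model` is a plain coefficient vector.
#' @return a single number.
#' @export
hlr_objective <- function(X, y, model, spec = NULL, intercept = 0) {
  if (inherits(model, "hlr_model")) {
    spec <- model$penalty
    beta <- model$beta
  } else beta <- model
  neg_log_likelihood(X, y, model, intercept) + penalty_value(spec, beta)
}

#' IRLS working response and weights
#'
#' One-term Taylor (IRLS) linearization of the logistic log-likelihood around
#' the current coefficients: fitted probabilities
#' \eqn{f_i = f(\beta_0 + X_i\beta)}, weights \eqn{W_i = f_i(1-f_i)} (floored
#' at `weight_floor` to keep the working response bounded at saturated fits)
#' and working responses \eqn{Z_i = \eta_i + (y_i - f_i)/W_i}.
#'
#' @param X numeric matrix (samples x features).
#' @param y binary 0/1 response.
#' @param beta current coefficient vector.
#' @param intercept current intercept.
#' @param weight_floor lower bound on the IRLS weights.
#' @param eps probability clipping bound, see [logistic_prob()].
#' @return a list with elements `Z`, `W` and `fitted`.
#' @export
irls_refresh <- function(X, y, beta, intercept = 0, weight_floor = 1e-5,
                         eps = 1e-10) {
  X <- as.matrix(X)
  eta <- drop(intercept + X %*% beta)
  fitted <- logistic_prob(eta, eps)
  W <- pmax(fitted * (1 - fitted), weight_floor)
  Z <- eta + (y - fitted) / W
  list(Z = Z, W = W, fitted = fitted)
}

#' Weighted partial-residual correlation for one coordinate
#'
#' The quantity \eqn{\omega_j = \sum_i W_i x_{ij} (Z_i - \check Z_i(j))}
#' driving the coordinate update, where
#' \eqn{\check Z_i(j) = \beta_0 + \sum_{k \ne j} x_{ik}\beta_k} is the partial
#' fit excluding feature `j`. Computed through the full residual
#' \eqn{Z - \beta_0 - X\beta}, which equals the literal leave-one-out
#' summation.
#'
#' @param j feature index (1-based).
#' @param X numeric matrix.
#' @param state an IRLS state from [irls_refresh()].
#' @param beta current coefficient vector.
#' @param intercept current intercept.
#' @return a single number \eqn{\omega_j}.
#' @export
coordinate_omega <- function(j, X, state, beta, intercept = 0) {
  X <- as.matrix(X)
  r <- state$Z - intercept - drop(X %*% beta)
  sum(state$W * X[, j] * (r + X[, j] * beta[j]))
}

# --- standardization -------------------------------------------------------

# center (when an intercept is fitted) and scale columns so sum x_ij^2 = 1;
# constant columns are dropped with a warning
standardize_x <- function(X, intercept, standardize) {
  p <- ncol(X)
  center <- if (intercept && standardize) colMeans(X) else rep(0, p)
  Xs <- sweep(X, 2, center, "-")
  scale <- if (standardize) sqrt(colSums(Xs^2)) else rep(1, p)
  keep <- scale > 1e-12
  if (!all(keep)) {
    warning(sprintf("dropping %d constant feature(s): %s", sum(!keep),
                    paste(utils::head(which(!keep), 5), collapse = ", ")),
            call. = FALSE)
    Xs <- Xs[, keep, drop = FALSE]
    scale <- scale[keep]
    center <- center[keep]
  }
  if (standardize) Xs <- sweep(Xs, 2, scale, "/")
  list(X = Xs, center = center, scale = scale, keep = keep)
}

check_xy <- function(X, y, binary = TRUE) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("`X` must be a numeric matrix", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("`X` must be finite (no NA/Inf)", call. = FALSE)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (nrow(X) < 2) stop("need at least 2 samples", call. = FALSE)
  if (binary) {
    if (!all(y %in% c(0, 1)))
      stop("`y` must be coded 0/1", call. = FALSE)
    if (length(unique(y)) < 2)
      stop("`y` contains a single class; both classes are required",
           call. = FALSE)
  } else if (anyNA(y) || any(!is.finite(y))) {
    stop("`y` must be finite numeric", call. = FALSE)
  }
  invisible(TRUE)
}

# smallest lambda at which every coefficient is thresholded to zero
# (slightly conservative for the hybrid families: the ridge term only widens
# the effective dead zone)
lambda_max_value <- function(Xs, y, alpha, operator, gaussian, intercept,
                             composed = FALSE, weight_floor = 1e-5) {
  if (gaussian) {
    b0 <- if (intercept) mean(y) else 0
    a <- pmax(colSums(Xs^2), 1e-12)
    omega <- drop(crossprod(Xs, y - b0))
    v <- abs(omega) / a
    lam1 <- if (operator == "half") max(((4 / 3) * v)^1.5) else max(v)
  } else {
    pbar <- if (intercept) mean(y) else 0.5
    w <- max(pbar * (1 - pbar), weight_floor)
    a <- pmax(w * colSums(Xs^2), 1e-12)
    omega <- abs(drop(crossprod(Xs, y - pbar)))
    lam1 <- if (operator == "half") {
      if (composed) max(((4 / 3) * omega / a)^1.5)
      else max((a / 2) * ((4 / 3) * omega / a)^1.5)
    } else {
      if (composed) max(omega / a) else max(omega)
    }
  }
  lam1 / max(alpha, 1e-3)
}

build_lambda_seq <- function(lmax, nlambda, lambda_min_ratio) {
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# assemble an hlr_model from one column of an engine result
make_model <- function(eng, l, std, p_full, feat_names, spec, options,
                       gaussian) {
  beta_std <- eng$beta[, l]
  beta <- numeric(p_full)
  beta[std$keep] <- beta_std / std$scale
  b0 <- eng$b0[l] - sum((beta_std / std$scale) * std$center)
  names(beta) <- feat_names
  structure(
    list(beta = beta, intercept = b0, penalty = spec,
         converged = eng$converged[l], n_outer_iters = eng$n_iter[l],
         final_objective = eng$objective[l], nzero = eng$nzero[l],
         n_safeguard = eng$n_safeguard[l], gaussian = gaussian,
         standardization = list(center = std$center, scale = std$scale,
                                keep = std$keep),
         options = options),
    class = "hlr_model")
}

default_options <- function(intercept, standardize, tol, max_outer, max_inner,
                            weight_floor, prob_eps) {
  list(intercept = intercept, standardize = standardize, tol = tol,
       max_outer = max_outer, max_inner = max_inner,
       weight_floor = weight_floor, prob_eps = prob_eps)
}

#' Fit penalized logistic regression by IRLS coordinate descent
#'
#' Fits the sparse logistic regression model with the penalty described by
#' `spec` (hybrid L1/2+L2 by default; Lasso, elastic net, ridge and pure L1/2
#' share the same engine). Features are standardized internally so
#' \eqn{\sum_i x_{ij}^2 = 1} (and centered when an intercept is fitted);
#' coefficients are returned on the original scale. The solver alternates
#' IRLS refreshes of the working response with full cyclic coordinate
#' sweeps (plus active-set iteration) until the largest coefficient change
#' falls below `tol`. Each coordinate update minimizes the penalized
#' quadratic surrogate exactly, so the unpenalized limit (`lambda = 0`)
#' coincides with maximum-likelihood logistic regression. Because the L1/2
#' term makes the objective non-convex, an objective-increase safeguard
#' monitors the outer loop: if the penalized objective rises, one damped
#' half-step is tried and on failure the previous iterate is restored.
#'
#' @param X numeric matrix, samples in rows.
#' @param y binary 0/1 response vector.
#' @param spec a [penalty_spec()] object.
#' @param intercept fit an unpenalized intercept (default `TRUE`).
#' @param standardize scale features internally (default `TRUE`).
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change, standardized scale.
#' @param max_outer maximum number of IRLS refreshes.
#' @param max_inner maximum coordinate sweeps per refresh.
#' @param weight_floor lower bound on IRLS weights.
#' @param prob_eps probability clipping bound.
#' @param beta_init optional warm-start coefficients (standardized scale).
#' @return an object of class `"hlr_model"`: coefficients `beta` (original
#'   scale, named), `intercept`, the `penalty`, convergence metadata
#'   (`converged`, `n_outer_iters`, `final_objective`, `n_safeguard`) and the
#'   standardization used.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60 * 10), 60, 10)
#' y <- rbinom(60, 1, plogis(X[, 1] * 2 - X[, 2]))
#' fit <- hlr_fit(X, y, penalty_spec("hlr", lambda = 0.5, alpha = 0.5))
#' coef(fit)
#' @seealso [hlr_path()], [cv_hlr()], [predict.hlr_model()]
#' @export
hlr_fit <- function(X, y, spec, intercept = TRUE, standardize = TRUE,
                    tol = 1e-4, max_outer = 100, max_inner = 100,
                    weight_floor = 1e-5, prob_eps = 1e-10,
                    beta_init = NULL,
                    update_rule = c("exact", "composed")) {
  update_rule <- match.arg(update_rule)
  X <- as.matrix(X)
  check_xy(X, y, binary = TRUE)
  if (!inherits(spec, "penalty_spec"))
    stop("`spec` must be a penalty_spec object", call. = FALSE)
  std <- standardize_x(X, intercept, standardize)
  p <- ncol(std$X)
  if (is.null(beta_init)) beta_init <- numeric(p)
  eng <- cd_engine(std$X, as.numeric(y), spec$lam1, spec$lam2,
                   spec$operator == "half", FALSE,
                   update_rule == "composed", intercept, tol,
                   max_outer, max_inner, weight_floor, prob_eps,
                   beta_init, 0)
  if (!eng$converged[1])
    warning("coordinate descent did not converge; increase max_outer",
            call. = FALSE)
  model <- make_model(eng, 1, std, ncol(X), colnames(X), spec,
                      default_options(intercept, standardize, tol, max_outer,
                                      max_inner, weight_floor, prob_eps),
                      gaussian = FALSE)
  model
}

#' Fit the penalized least-squares (Gaussian) model
#'
#' Squared-error analogue of [hlr_fit()]: minimizes
#' \eqn{\|y - \beta_0 - X\beta\|_2^2 + \lambda(\alpha\|\beta\|_{1/2} +
#' (1-\alpha)\|\beta\|_2^2)} with no IRLS layer. The coordinate rule is the
#' thresholding-then-ridge composition
#' `hlr_update(omega_j / a_j, spec)` with \eqn{a_j = \sum_i x_{ij}^2}
#' (so with unit-norm columns it is exactly the univariate operator of
#' [hlr_update()]); in an orthogonal design the solution therefore decouples
#' into [orthogonal_path()] applied to the OLS coordinates, and the
#' shrunken-Gram equivalence with the pure L1/2 problem holds exactly.
#'
#' @inheritParams hlr_fit
#' @param y numeric response vector.
#' @return an `"hlr_model"` object (with `gaussian = TRUE`).
#' @export
hlr_fit_gaussian <- function(X, y, spec, intercept = TRUE, standardize = TRUE,
                             tol = 1e-4, max_outer = 100, max_inner = 100,
                             beta_init = NULL) {
  X <- as.matrix(X)
  check_xy(X, y, binary = FALSE)
  if (!inherits(spec, "penalty_spec"))
    stop("`spec` must be a penalty_spec object", call. = FALSE)
  std <- standardize_x(X, intercept, standardize)
  p <- ncol(std$X)
  if (is.null(beta_init)) beta_init <- numeric(p)
  eng <- cd_engine(std$X, as.numeric(y), spec$lam1, spec$lam2,
                   spec$operator == "half", TRUE, TRUE, intercept, tol,
                   max_outer, max_inner, 1e-5, 1e-10, beta_init, 0)
  if (!eng$converged[1])
    warning("coordinate descent did not converge; increase max_inner",
            call. = FALSE)
  make_model(eng, 1, std, ncol(X), colnames(X), spec,
             default_options(intercept, standardize, tol, max_outer,
                             max_inner, NA, NA),
             gaussian = TRUE)
}

#' Warm-started regularization path
#'
#' Fits the model over a decreasing sequence of `lambda` values at fixed
#' `alpha`, warm-starting each solution from the previous one. When `lambda`
#' is not supplied, a log-spaced grid of `nlambda` values is built from
#' `lambda_max` (the smallest strength that zeroes every coefficient, derived
#' from the dead-zone radius of the thresholding operator) down to
#' `lambda_min_ratio * lambda_max`.
#'
#' @inheritParams hlr_fit
#' @param family penalty family, see [penalty_spec()].
#' @param alpha mixing weight for the `"hlr"` / `"en"` families.
#' @param lambda optional user-supplied decreasing sequence.
#' @param nlambda grid length when `lambda` is `NULL`.
#' @param lambda_min_ratio ratio of the smallest to the largest grid value.
#' @return an object of class `"hlr_path"`: `lambda`, `alpha`, `family`,
#'   matrix `beta` (features x lambda, original scale), `intercept`, `nzero`,
#'   `converged`, and the standardization.
#' @export
hlr_path <- function(X, y, family = "hlr", alpha = 0.5, lambda = NULL,
                     nlambda = 30, lambda_min_ratio = 0.01,
                     intercept = TRUE, standardize = TRUE, tol = 1e-4,
                     max_outer = 100, max_inner = 100, weight_floor = 1e-5,
                     prob_eps = 1e-10,
                     update_rule = c("exact", "composed")) {
  update_rule <- match.arg(update_rule)
  X <- as.matrix(X)
  check_xy(X, y, binary = TRUE)
  family <- method_family(family)
  spec0 <- penalty_spec(family, lambda = 1, alpha = alpha)
  std <- standardize_x(X, intercept, standardize)
  if (is.null(lambda)) {
    lmax <- lambda_max_value(std$X, y, spec0$alpha, spec0$operator,
                             gaussian = FALSE, intercept = intercept,
                             composed = update_rule == "composed",
                             weight_floor = weight_floor)
    lambda <- build_lambda_seq(lmax, nlambda, lambda_min_ratio)
  } else {
    if (anyDuplicated(lambda)) {
      warning("duplicated lambda values removed", call. = FALSE)
      lambda <- unique(lambda)
    }
    lambda <- sort(lambda, decreasing = TRUE)
  }
  lam1 <- lambda * spec0$alpha
  lam2 <- lambda * (1 - spec0$alpha)
  eng <- cd_engine(std$X, as.numeric(y), lam1, lam2,
                   spec0$operator == "half", FALSE,
                   update_rule == "composed", intercept, tol,
                   max_outer, max_inner, weight_floor, prob_eps,
                   numeric(ncol(std$X)), 0)
  beta <- matrix(0, ncol(X), length(lambda))
  beta[std$keep, ] <- eng$beta / std$scale
  b0 <- eng$b0 - drop(crossprod(eng$beta / std$scale, std$center))
  rownames(beta) <- colnames(X)
  structure(
    list(lambda = lambda, alpha = spec0$alpha, family = family,
         beta = beta, intercept = b0, nzero = eng$nzero,
         converged = eng$converged, n_safeguard = eng$n_safeguard,
         standardization = list(center = std$center, scale = std$scale,
                                keep = std$keep),
         options = default_options(intercept, standardize, tol, max_outer,
                                   max_inner, weight_floor, prob_eps)),
    class = "hlr_path")
}

# extract a single-lambda hlr_model from a path
path_model <- function(path, l) {
  spec <- penalty_spec(path$family, lambda = path$lambda[l],
                       alpha = path$alpha)
  structure(
    list(beta = path$beta[, l], intercept = path$intercept[l],
         penalty = spec, converged = path$converged[l],
         n_outer_iters = NA_integer_, final_objective = NA_real_,
         nzero = path$nzero[l], n_safeguard = path$n_safeguard[l],
         gaussian = FALSE, standardization = path$standardization,
         options = path$options),
    class = "hlr_model")
}

#' Predict from a fitted model
#'
#' @param object an `"hlr_model"`.
#' @param newdata numeric matrix with the same number of features the model
#'   was trained on.
#' @param type `"response"` for probabilities, `"class"` for 0/1 labels,
#'   `"link"` for the linear predictor.
#' @param threshold classification cutoff; probabilities `>= threshold` map
#'   to class 1 (ties go to 1).
#' @param ... unused.
#' @return numeric vector (probabilities or linear predictor) or integer
#'   vector of labels.
#' @export
predict.hlr_model <- function(object, newdata,
                              type = c("response", "class", "link"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object$beta), call. = FALSE)
  eta <- drop(object$intercept + newdata %*% object$beta)
  switch(type,
         link = eta,
         response = logistic_prob(eta),
         class = as.integer(logistic_prob(eta) >= threshold))
}

#' @export
coef.hlr_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
print.hlr_model <- function(x, ...) {
  cat(sprintf("<hlr_model> %s fit: %d/%d nonzero, intercept %.4f\n",
              if (x$gaussian) "gaussian" else "logistic",
              x$nzero, length(x$beta), x$intercept))
  print(x$penalty)
  cat(sprintf("  converged: %s (outer iters %s, objective %.5g)\n",
              x$converged, x$n_outer_iters, x$final_objective))
  invisible(x)
}

#' @export
print.hlr_path <- function(x, ...) {
  cat(sprintf("<hlr_path> family=%s alpha=%g, %d lambda values [%.4g .. %.4g]\n",
              x$family, x$alpha, length(x$lambda), max(x$lambda),
              min(x$lambda)))
  cat("  nonzero counts:", paste(x$nzero, collapse = " "), "\n")
  invisible(x)
}

#' Write a fitted model to flat text
#'
#' Coefficients go to `<file>` as a two-column TSV (feature, coefficient);
#' penalty, options, convergence metadata and standardization go to a JSON
#' sidecar `<file>.json`.
#'
#' @param model an `"hlr_model"`.
#' @param file output TSV path.
#' @return `file`, invisibly.
#' @export
write_hlr_model <- function(model, file) {
  feats <- names(model$beta)
  if (is.null(feats)) feats <- paste0("V", seq_along(model$beta))
  df <- data.frame(feature = c("(Intercept)", feats),
                   coefficient = c(model$intercept, unname(model$beta)))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    penalty = model$penalty[c("family", "lambda", "alpha", "lam1", "lam2",
                              "operator")],
    gaussian = model$gaussian, converged = model$converged,
    n_outer_iters = model$n_outer_iters,
    final_objective = model$final_objective, nzero = model$nzero,
    n_safeguard = model$n_safeguard, options = model$options,
    standardization = model$standardization)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' Read a model written by [write_hlr_model()]
#'
#' @param file TSV path previously written by [write_hlr_model()].
#' @return an `"hlr_model"` object sufficient for prediction.
#' @export
read_hlr_model <- function(file) {
  df <- read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  is_int <- df$feature == "(Intercept)"
  beta <- df$coefficient[!is_int]
  names(beta) <- df$feature[!is_int]
  spec <- penalty_spec(meta$penalty$family, lambda = meta$penalty$lambda,
                       alpha = meta$penalty$alpha)
  structure(
    list(beta = beta, intercept = df$coefficient[is_int][1], penalty = spec,
         converged = meta$converged, n_outer_iters = meta$n_outer_iters,
         final_objective = meta$final_objective, nzero = meta$nzero,
         n_safeguard = meta$n_safeguard, gaussian = isTRUE(meta$gaussian),
         standardization = meta$standardization, options = meta$options),
    class = "hlr_model")
}
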