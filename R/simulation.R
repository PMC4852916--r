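#' Simulation scenario specification
#'
#' Four benchmark scenarios for sparse logistic regression with grouped
#' correlated predictors, all with `p = 1000` features drawn i.i.d. standard
#' normal before correlation is injected. Within each group the member
#' columns are overwritten as
#' \eqn{x_i \leftarrow \rho\, x_{\mathrm{anchor}} + (1-\rho)\, x_i}, and
#' labels come from the latent-logit model
#' \eqn{\mathrm{logit}(p_i) = X_i\beta + \sigma\varepsilon_i},
#' \eqn{\varepsilon_i \sim N(0,1)}, with \eqn{y_i = 1} iff
#' \eqn{p_i > 0.5} (see [generate_scenario()] for the label mechanism and
#' its Bernoulli alternative).
#'
#' \describe{
#'   \item{1}{100/100 train/test, `sigma = 0.3`,
#'     `beta = (2,2,2,2,2, 0 x 995)`; group 1 -> 2:5.}
#'   \item{2}{as 1 but `beta = (2,2,2,2,2,1.5,-2,1.7,3,-2.5, 0 x 990)`.}
#'   \item{3}{200/200, `sigma = 0.4`, the 10 coefficients of scenario 2
#'     followed by twenty 3s (support 30); groups 1 -> 2:5 and 11 -> 12:30.}
#'   \item{4}{400/400, `sigma = 0.4`, 200 nonzero coefficients
#'     (30 x 3, (-2.5, 2, -1.5, 1.8, -2.5), 40 x 3, 25 x 2, 30 x 3, 70 x 2)
#'     and 800 zeros; groups 1 -> 2:30, 36 -> 37:75, 101 -> 102:130.}
#' }
#'
#' @param id scenario number, 1 to 4.
#' @param rho correlation coefficient of the grouped variables.
#' @param n_train,n_test optional overrides of the scenario sample sizes.
#' @return a list of class `"scenario_spec"` with elements `id`, `rho`,
#'   `n_train`, `n_test`, `p`, `sigma`, `beta_true`, `groups`.
#' @export
scenario_spec <- function(id, rho, n_train = NULL, n_test = NULL) {
  if (!id %in% 1:4) stop("scenario `id` must be 1, 2, 3 or 4", call. = FALSE)
  if (!is.numeric(rho) || rho < 0 || rho > 1)
    stop("`rho` must be in [0, 1]", call. = FALSE)
  p <- 1000
  base10 <- c(2, 2, 2, 2, 2, 1.5, -2, 1.7, 3, -2.5)
  sp <- switch(as.character(id),
    "1" = list(n = 100, sigma = 0.3,
               beta = c(rep(2, 5), rep(0, 995)),
               groups = list(list(anchor = 1L, members = 2:5))),
    "2" = list(n = 100, sigma = 0.3,
               beta = c(base10, rep(0, 990)),
               groups = list(list(anchor = 1L, members = 2:5))),
    "3" = list(n = 200, sigma = 0.4,
               beta = c(base10, rep(3, 20), rep(0, 970)),
               groups = list(list(anchor = 1L, members = 2:5),
                             list(anchor = 11L, members = 12:30))),
    "4" = list(n = 400, sigma = 0.4,
               beta = c(rep(3, 30), c(-2.5, 2, -1.5, 1.8, -2.5), rep(3, 40),
                        rep(2, 25), rep(3, 30), rep(2, 70), rep(0, 800)),
               groups = list(list(anchor = 1L, members = 2:30),
                             list(anchor = 36L, members = 37:75),
                             list(anchor = 101L, members = 102:130))))
  structure(
    list(id = id, rho = rho,
         n_train = if (is.null(n_train)) sp$n else n_train,
         n_test = if (is.null(n_test)) sp$n else n_test,
         p = p, sigma = sp$sigma, beta_true = sp$beta, groups = sp$groups),
    class = "scenario_spec")
}

# one simulated block (X, y) under a scenario
simulate_block <- function(spec, n, seed, mechanism) {
  with_local_seed(seed, {
    X <- matrix(rnorm(n * spec$p), n, spec$p)
    for (g in spec$groups)
      X[, g$members] <- spec$rho * X[, g$anchor] +
        (1 - spec$rho) * X[, g$members]
    eta <- drop(X %*% spec$beta_true) + spec$sigma * rnorm(n)
    pr <- plogis(eta)
    y <- if (mechanism == "bernoulli") rbinom(n, 1, pr)
         else as.integer(pr > 0.5)
    list(X = X, y = y)
  })
}

#' Generate a simulated dataset
#'
#' Draws independent train and test blocks under a [scenario_spec()] (the
#' two blocks use sub-seeds derived from `seed`, so generation is fully
#' deterministic given `seed`). The latent class probability is
#' \eqn{p_i = \mathrm{logistic}(X_i\beta + \sigma\varepsilon_i)}; the
#' default label mechanism thresholds it, \eqn{y_i = 1} iff
#' \eqn{p_i > 0.5}, so label noise enters only through the latent
#' perturbation \eqn{\sigma\varepsilon}. This is the reading under which
#' near-perfect test accuracy is attainable when the support is recovered;
#' the alternative `"bernoulli"` mechanism draws
#' \eqn{y_i \sim \mathrm{Bernoulli}(p_i)}, which caps the achievable
#' accuracy at the Bayes level (about 90-94% for scenario 1) regardless of
#' the estimator.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer seed.
#' @param mechanism `"deterministic"` (default) or `"bernoulli"`.
#' @return an object of class `"sim_dataset"` with `X_train`, `y_train`,
#'   `X_test`, `y_test`, `beta_true`, `spec`, `seed`.
#' @export
generate_scenario <- function(spec, seed = 1,
                              mechanism = c("deterministic", "bernoulli")) {
  mechanism <- match.arg(mechanism)
  if (!inherits(spec, "scenario_spec"))
    stop("`spec` must be a scenario_spec object", call. = FALSE)
  tr <- simulate_block(spec, spec$n_train, derive_seed(seed, 1L), mechanism)
  te <- simulate_block(spec, spec$n_test, derive_seed(seed, 2L), mechanism)
  structure(
    list(X_train = tr$X, y_train = tr$y, X_test = te$X, y_test = te$y,
         beta_true = spec$beta_true, spec = spec, seed = seed,
         mechanism = mechanism),
    class = "sim_dataset")
}

#' Feature-selection quality metrics
#'
#' Compares the supports (nonzero patterns) of the true and estimated
#' coefficient vectors:
#' \deqn{TP = |\beta \,.\!* \hat\beta|_0,\quad
#'       FP = |\bar\beta \,.\!* \hat\beta|_0,\quad
#'       FN = |\beta \,.\!* \bar{\hat\beta}|_0,\quad
#'       TN = |\bar\beta \,.\!* \bar{\hat\beta}|_0,}
#' where the bar is the logical "not" of the support indicator and
#' \eqn{|\cdot|_0} counts nonzeros; sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP). Test-set accuracy is attached when labels are supplied.
#'
#' @param beta_true,beta_hat equal-length coefficient vectors.
#' @param y_test,y_pred optional test labels and predictions.
#' @return a list of class `"selection_metrics"` with `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity` and (optionally) `test_accuracy`.
#' @export
selection_metrics <- function(beta_true, beta_hat, y_test = NULL,
                              y_pred = NULL) {
  if (length(beta_true) != length(beta_hat))
    stop("coefficient vectors must have equal length", call. = FALSE)
  s_true <- beta_true != 0
  s_hat <- beta_hat != 0
  tp <- sum(s_true & s_hat)
  fp <- sum(!s_true & s_hat)
  fn <- sum(s_true & !s_hat)
  tn <- sum(!s_true & !s_hat)
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
              specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
              test_accuracy = if (!is.null(y_test)) accuracy(y_test, y_pred)
                              else NA_real_)
  class(out) <- "selection_metrics"
  out
}

#' @export
print.selection_metrics <- function(x, ...) {
  cat(sprintf(
    "<selection_metrics> TP=%d FP=%d TN=%d FN=%d  sens=%.3f spec=%.3f acc=%.4f\n",
    x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity, x$test_accuracy))
  invisible(x)
}

method_family <- function(method) {
  switch(tolower(method),
         lasso = "l1", l1 = "l1", half = "half", "l1/2" = "half",
         en = "en", elasticnet = "en", hlr = "hlr", ridge = "l2",
         l2 = "l2",
         stop("unknown method: ", method, call. = FALSE))
}

#' Simulation benchmark over scenarios, correlations and methods
#'
#' For every (scenario, rho, method) cell and every repeat: generate a fresh
#' dataset, tune (lambda, alpha) by K-fold cross-validation on the training
#' block, refit on the full training block at the selected cell, classify
#' the test block at the 0.5 cutoff, and score support recovery against the
#' true coefficients. Per-repeat seeds are derived reproducibly from `seed`,
#' so two invocations with the same arguments give identical tables. A
#' failed repeat (e.g. a degenerate fold) is recorded and excluded.
#'
#' @param scenarios integer vector of scenario ids (see [scenario_spec()]).
#' @param rhos numeric vector of group-correlation coefficients.
#' @param methods character vector from `"lasso"`, `"half"` (pure L1/2),
#'   `"en"`, `"hlr"`.
#' @param n_repeats simulation repeats per cell.
#' @param seed master seed.
#' @param k CV folds.
#' @param nlambda,alphas,lambda_min_ratio CV grid controls, see [cv_hlr()].
#' @param intercept fit an intercept (default `FALSE`: the simulated
#'   decision boundary passes through the origin, matching the
#'   intercept-free form of the model).
#' @param mechanism label mechanism, see [generate_scenario()].
#' @param verbose print one line per repeat.
#' @return a `data.frame` with one row per cell: mean and standard error of
#'   sensitivity, specificity and test accuracy (proportions), the mean
#'   number of selected features, and the failure count.
#' @export
run_benchmark <- function(scenarios = 1, rhos = c(0.3, 0.6, 0.9),
                          methods = "hlr", n_repeats = 50, seed = 1,
                          k = 10, nlambda = 30, alphas = NULL,
                          lambda_min_ratio = 0.01, intercept = FALSE,
                          mechanism = "deterministic", verbose = FALSE) {
  if (n_repeats < 1) stop("`n_repeats` must be >= 1", call. = FALSE)
  rows <- list()
  for (sc in scenarios) for (rho in rhos) for (m in methods) {
    fam <- method_family(m)
    sens <- spec_ <- acc <- nsel <- rep(NA_real_, n_repeats)
    nfail <- 0L
    for (r in seq_len(n_repeats)) {
      rep_seed <- derive_seed(seed, sc * 1000000L + round(rho * 100) * 1000L + r)
      res <- tryCatch({
        dat <- generate_scenario(scenario_spec(sc, rho), seed = rep_seed,
                                 mechanism = mechanism)
        cv <- suppressWarnings(
          cv_hlr(dat$X_train, dat$y_train, family = fam, alphas = alphas,
                 nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                 k = k, seed = derive_seed(rep_seed, 3L),
                 intercept = intercept))
        y_hat <- predict(cv$fit, dat$X_test, type = "class")
        selection_metrics(dat$beta_true, cv$fit$beta, dat$y_test, y_hat)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        nfail <- nfail + 1L
        if (verbose) message(sprintf("  repeat %d failed: %s", r,
                                     conditionMessage(res)))
        next
      }
      sens[r] <- res$sensitivity
      spec_[r] <- res$specificity
      acc[r] <- res$test_accuracy
      nsel[r] <- res$tp + res$fp
      if (verbose)
        message(sprintf(
          "scenario %d rho %.1f %s repeat %d: acc %.3f sens %.3f spec %.3f",
          sc, rho, m, r, res$test_accuracy, res$sensitivity,
          res$specificity))
    }
    se <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = sc, rho = rho, method = m,
      n_repeats = n_repeats, n_failed = nfail,
      sensitivity = mean(sens, na.rm = TRUE), sensitivity_se = se(sens),
      specificity = mean(spec_, na.rm = TRUE), specificity_se = se(spec_),
      accuracy = mean(acc, na.rm = TRUE), accuracy_se = se(acc),
      mean_selected = mean(nsel, na.rm = TRUE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a benchmark results table as TSV
#'
#' @param results a `data.frame` from [run_benchmark()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_benchmark_tsv <- function(results, file) {
  write.table(results, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
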