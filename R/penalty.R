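#' Penalty specification
#'
#' Describes one member of the penalty families supported by the solver:
#' \describe{
#'   \item{`"l1"`}{Lasso, \eqn{\lambda \|\beta\|_1}.}
#'   \item{`"l2"`}{ridge, \eqn{\lambda \|\beta\|_2^2}.}
#'   \item{`"half"`}{pure L1/2, \eqn{\lambda \|\beta\|_{1/2}}.}
#'   \item{`"hlr"`}{hybrid L1/2+L2,
#'     \eqn{\lambda(\alpha\|\beta\|_{1/2} + (1-\alpha)\|\beta\|_2^2)}.}
#'   \item{`"en"`}{elastic net,
#'     \eqn{\lambda(\alpha\|\beta\|_1 + (1-\alpha)\|\beta\|_2^2)}.}
#' }
#' `"half"` is identical to `"hlr"` with `alpha = 1`, and `"l2"` to `"hlr"`
#' with `alpha = 0`; for the single-penalty families the supplied `alpha` is
#' ignored. Internally the penalty is carried as the pair
#' \eqn{\lambda_1 = \lambda\alpha} (sparsity weight, fed to the thresholding
#' operator) and \eqn{\lambda_2 = \lambda(1-\alpha)} (ridge weight).
#'
#' @param family one of `"hlr"`, `"l1"`, `"l2"`, `"half"`, `"en"`.
#' @param lambda overall penalty strength, a single non-negative number.
#' @param alpha mixing weight in `[0, 1]`; only used by `"hlr"` and `"en"`.
#' @return an object of class `"penalty_spec"` with elements `family`,
#'   `lambda`, `alpha`, `lam1`, `lam2` and `operator` (`"half"` or `"soft"`).
#' @examples
#' penalty_spec("hlr", lambda = 1, alpha = 0.5)
#' penalty_spec("l1", lambda = 0.2)
#' @export
penalty_spec <- function(family = c("hlr", "l1", "l2", "half", "en"),
                         lambda, alpha = 1) {
  family <- match.arg(family)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop("`lambda` must be a single finite non-negative number", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1)
    stop("`alpha` must be a single number in [0, 1]", call. = FALSE)
  alpha_eff <- switch(family, l1 = 1, half = 1, l2 = 0, alpha)
  structure(
    list(family = family, lambda = lambda, alpha = alpha_eff,
         lam1 = lambda * alpha_eff, lam2 = lambda * (1 - alpha_eff),
         operator = if (family %in% c("l1", "en")) "soft" else "half"),
    class = "penalty_spec")
}

#' Penalty specification from the (lambda1, lambda2) parameterization
#'
#' Alternative constructor using the two separate penalty weights: `lam1` on
#' the sparsity norm (L1/2 or L1) and `lam2` on the squared L2 norm. The
#' equivalent overall strength is `lambda = lam1 + lam2` with mixing
#' `alpha = lam1 / (lam1 + lam2)`.
#'
#' @param lam1 non-negative weight on the sparsity-inducing norm.
#' @param lam2 non-negative weight on the ridge norm.
#' @param operator `"half"` for L1/2-type thresholding, `"soft"` for L1.
#' @return a `"penalty_spec"` object; its `shrinkage_delta` element holds
#'   \eqn{\delta = \lambda_2 / (1 + \lambda_2)}, the weight with which the
#'   ridge term shrinks the Gram matrix towards the identity.
#' @export
penalty_spec_lambda12 <- function(lam1, lam2, operator = c("half", "soft")) {
  operator <- match.arg(operator)
  if (!is.numeric(lam1) || lam1 < 0 || !is.numeric(lam2) || lam2 < 0)
    stop("`lam1` and `lam2` must be non-negative", call. = FALSE)
  lambda <- lam1 + lam2
  alpha <- if (lambda > 0) lam1 / lambda else 1
  family <- if (operator == "half") {
    if (lam2 == 0) "half" else if (lam1 == 0) "l2" else "hlr"
  } else {
    if (lam2 == 0) "l1" else "en"
  }
  spec <- penalty_spec(family, lambda = lambda, alpha = alpha)
  spec$lam1 <- lam1
  spec$lam2 <- lam2
  spec$shrinkage_delta <- lam2 / (1 + lam2)
  spec
}

# penalty value lam1 * sum sqrt|b| (or lam1 * sum |b| for soft) + lam2 * sum b^2
penalty_value <- function(spec, beta) {
  sparse_part <- if (spec$operator == "half") sum(sqrt(abs(beta)))
                 else sum(abs(beta))
  spec$lam1 * sparse_part + spec$lam2 * sum(beta^2)
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat(sprintf("<penalty_spec> family=%s lambda=%g alpha=%g (lam1=%g, lam2=%g)\n",
              x$family, x$lambda, x$alpha, x$lam1, x$lam2))
  invisible(x)
}
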