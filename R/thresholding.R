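#' Half-thresholding operator
#'
#' Closed-form univariate solution rule for the L1/2-penalized least-squares
#' subproblem. For `|omega|` above the dead-zone radius
#' \eqn{(3/4)\lambda^{2/3}} it returns
#' \deqn{\frac{2}{3}\,\omega\left(1 + \cos\frac{2(\pi - \varphi_\lambda(\omega))}{3}\right),
#'   \qquad \varphi_\lambda(\omega) = \arccos\!\left(\frac{\lambda}{8}
#'   \left(\frac{|\omega|}{3}\right)^{-3/2}\right),}
#' and exactly 0 otherwise (the boundary maps to 0). On its non-zero branch
#' this is the minimizer of \eqn{(b-\omega)^2 + \lambda\sqrt{|b|}}; unlike
#' soft thresholding it is asymptotically unbiased: the shrinkage vanishes as
#' `|omega|` grows. \eqn{\pi} is used at machine precision.
#'
#' @param omega numeric vector of unpenalized (OLS-type) coordinate values.
#' @param lambda single non-negative threshold strength.
#' @return numeric vector of the same length as `omega`.
#' @examples
#' half_threshold(0.7, 1)   # inside the dead zone (radius 0.75): 0
#' half_threshold(2, 1)     # approx 1.814
#' half_threshold(5, 0)     # identity at lambda = 0
#' @seealso [soft_threshold()], [hlr_update()]
#' @export
half_threshold <- function(omega, lambda) {
  check_omega_lambda(omega, lambda)
  if (lambda == 0) return(omega)
  out <- numeric(length(omega))
  aw <- abs(omega)
  active <- aw > 0.75 * lambda^(2 / 3)
  if (any(active)) {
    phi <- acos((lambda / 8) * (aw[active] / 3)^(-1.5))
    out[active] <- (2 / 3) * omega[active] *
      (1 + cos(2 * (pi - phi) / 3))
  }
  out
}

#' Soft-thresholding operator
#'
#' The Lasso coordinate rule \eqn{\mathrm{sign}(\omega)\max(|\omega| -
#' \lambda, 0)}, i.e. the minimizer of
#' \eqn{\tfrac12 (b-\omega)^2 + \lambda |b|}.
#'
#' @inheritParams half_threshold
#' @return numeric vector of the same length as `omega`.
#' @examples
#' soft_threshold(2, 0.5)    # 1.5
#' soft_threshold(-0.3, 0.5) # 0
#' @export
soft_threshold <- function(omega, lambda) {
  check_omega_lambda(omega, lambda)
  sign(omega) * pmax(abs(omega) - lambda, 0)
}

check_omega_lambda <- function(omega, lambda) {
  if (!is.numeric(omega) || anyNA(omega) || any(!is.finite(omega)))
    stop("`omega` must be finite numeric", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop("`lambda` must be a single finite non-negative number", call. = FALSE)
  invisible(TRUE)
}

#' Penalized coordinate update
#'
#' Maps an unpenalized coordinate value through the univariate update rule of
#' the given penalty family:
#' \describe{
#'   \item{hlr / half / l2}{`half_threshold(omega, lambda * alpha) /
#'     (1 + lambda * (1 - alpha))` — half-thresholding followed by ridge
#'     shrinkage.}
#'   \item{en}{`soft_threshold(omega, lambda * alpha) /
#'     (1 + lambda * (1 - alpha))`.}
#'   \item{l1}{`soft_threshold(omega, lambda)`.}
#' }
#'
#' @param omega numeric vector of coordinate values.
#' @param spec a [penalty_spec()] object.
#' @return numeric vector of updated coefficients.
#' @examples
#' hlr_update(5, penalty_spec("l2", lambda = 2))            # 5 / 3
#' hlr_update(2, penalty_spec("hlr", lambda = 1, alpha = 1)) # = half_threshold(2, 1)
#' @export
hlr_update <- function(omega, spec) {
  if (!inherits(spec, "penalty_spec"))
    stop("`spec` must be a penalty_spec object", call. = FALSE)
  thresh <- if (spec$operator == "half") half_threshold else soft_threshold
  thresh(omega, spec$lam1) / (1 + spec$lam2)
}

#' Orthogonal-design solution path
#'
#' In an orthogonal design the penalized least-squares problem decouples and
#' each coefficient is obtained by passing its OLS value through the
#' univariate update of the penalty. Useful for drawing the classic
#' operator-shape curves (Lasso bias, L1/2 dead zone plus asymptotic
#' unbiasedness, elastic-net double shrinkage, and their hybrid).
#'
#' @param spec a [penalty_spec()] object.
#' @param ols_values numeric vector of OLS coordinate estimates.
#' @return numeric vector of penalized estimates, same length as `ols_values`.
#' @examples
#' orthogonal_path(penalty_spec("l1", lambda = 0.1), 1.0)  # 0.9
#' @export
orthogonal_path <- function(spec, ols_values) {
  hlr_update(ols_values, spec)
}
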