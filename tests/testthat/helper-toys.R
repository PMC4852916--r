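# shared fixtures and independent oracles, all generated in code

# small logistic dataset with a couple of informative features
make_logistic_toy <- function(n = 60, p = 6, seed = 1, beta = NULL,
                              intercept = 0) {
  if (is.null(beta)) beta <- c(1.5, -1, rep(0, p - 2))
  with_local <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  with_local({
    X <- matrix(rnorm(n * p), n, p)
    pr <- plogis(intercept + drop(X %*% beta))
    y <- rbinom(n, 1, pr)
    # guarantee both classes
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    list(X = X, y = y, beta = beta)
  })
}

# brute-force grid minimizer of the univariate half-penalized objective
#   g(b) = (b - omega)^2 + lam * sqrt(|b|)
grid_min_half <- function(omega, lam, lim = NULL, h = 1e-4) {
  if (is.null(lim)) lim <- abs(omega) + 1
  g <- seq(-lim, lim, by = h)
  obj <- (g - omega)^2 + lam * sqrt(abs(g))
  g[which.min(obj)]
}

# literal double-loop evaluation of the weighted partial-residual correlation
omega_brute <- function(j, X, state, beta, intercept = 0) {
  n <- nrow(X)
  total <- 0
  for (i in seq_len(n)) {
    zcheck <- intercept
    for (k in seq_len(ncol(X))) if (k != j)
      zcheck <- zcheck + X[i, k] * beta[k]
    total <- total + state$W[i] * X[i, j] * (state$Z[i] - zcheck)
  }
  total
}

# penalized IRLS surrogate 0.5 * sum W (Z - b0 - X b)^2 + penalty
surrogate_value <- function(X, state, beta, b0, spec) {
  r <- state$Z - b0 - drop(X %*% beta)
  0.5 * sum(state$W * r^2) + penalty_value_oracle(spec, beta)
}

# penalty recomputed independently of the package internals
penalty_value_oracle <- function(spec, beta) {
  sparse <- if (spec$operator == "half") sum(sqrt(abs(beta)))
            else sum(abs(beta))
  spec$lam1 * sparse + spec$lam2 * sum(beta^2)
}

# one exact coordinate update as the logistic engine performs it
engine_update <- function(j, X, state, beta, b0, spec) {
  a_j <- sum(state$W * X[, j]^2)
  om <- coordinate_omega(j, X, state, beta, b0)
  denom <- a_j + 2 * spec$lam2
  if (spec$operator == "half") {
    half_threshold(om / denom, 2 * spec$lam1 / denom)
  } else {
    soft_threshold(om, spec$lam1) / denom
  }
}

# exhaustive pair-counting AUC (ties count one half)
auc_pairs <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
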