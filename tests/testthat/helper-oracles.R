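# Independent oracles used across the test files.

# Moment of the (unnormalised) GIG density by adaptive quadrature on (0, Inf)
# via the bounded change of variable x = t / (1 - t).
quad_gig_moment <- function(index, coef_x, coef_invx, power = 1,
                            rel.tol = 1e-12) {
  f <- function(x) x^(index - 1) * exp(-(coef_x * x + coef_invx / x) / 2)
  # rescale the integrand by its value near the mode to avoid underflow
  xm <- (index - 1 + sqrt((index - 1)^2 + coef_x * coef_invx)) / coef_x
  if (xm <= 0) xm <- sqrt(coef_invx / coef_x)
  lf0 <- (index - 1) * log(xm) - (coef_x * xm + coef_invx / xm) / 2
  g <- function(t, k) {
    x <- t / (1 - t)
    exp((index - 1) * log(x) - (coef_x * x + coef_invx / x) / 2 - lf0 +
          k * log(x)) / (1 - t)^2
  }
  Z <- stats::integrate(g, 0, 1, k = 0, rel.tol = rel.tol,
                        subdivisions = 500L)$value
  m <- stats::integrate(g, 0, 1, k = power, rel.tol = rel.tol,
                        subdivisions = 500L)$value
  m / Z
}

# quadrature over (0, 1) for shrinkage-weight densities
quad_unit <- function(f, rel.tol = 1e-10) {
  stats::integrate(f, 0, 1, rel.tol = rel.tol, subdivisions = 500L)$value
}

# direct dense solve oracle for the coefficient update
beta_update_oracle <- function(X, y, a, b, g) {
  A <- crossprod(X) + diag(g * b, ncol(X))
  list(mean = drop(solve(A, crossprod(X, y))), cov = solve(A) / a)
}

# tiny deterministic toy regression
toy_regression <- function(n = 30, p = 5, seed = 42, sd = 0.5) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  beta <- c(2, -1, rep(0, p - 2))
  y <- drop(X %*% beta) + rnorm(n, sd = sd)
  list(X = X, y = y - mean(y), beta = beta)
}
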