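test_that("coefficient update solves the penalized normal equations", {
  # scalar case: X = 1, y = 2, unit precisions
  up <- vb_update_beta(matrix(1), 2, a = 1, b = 1, g = 1)
  expect_equal(up$mean, 1)
  expect_equal(drop(up$cov), 1 / 2)
  # vanishing penalty recovers least squares on a full-rank tall design
  toy <- toy_regression(n = 40, p = 3)
  up0 <- vb_update_beta(toy$X, toy$y, a = 1, b = rep(1, 3), g = 1e-12)
  ls <- drop(solve(crossprod(toy$X), crossprod(toy$X, toy$y)))
  expect_equal(up0$mean, ls, tolerance = 1e-8)
  # random instance against the dense solve oracle
  set.seed(8)
  X <- matrix(rnorm(15), 5, 3)
  y <- rnorm(5)
  b <- runif(3, 0.5, 2)
  up2 <- vb_update_beta(X, y, a = 0.7, b = b, g = 1.3)
  orc <- beta_update_oracle(X, y, 0.7, b, 1.3)
  expect_equal(up2$mean, orc$mean, tolerance = 1e-10)
  expect_equal(up2$cov, orc$cov, tolerance = 1e-10)
  expect_true(isSymmetric(up2$cov))
  expect_true(all(eigen(up2$cov, only.values = TRUE)$values > 0))
})

test_that("variance-component parameter updates match direct arithmetic", {
  expect_equal(vb_update_delta(1, 1, rep(0, 3), rep(0, 3), 2), rep(2, 3))
  expect_equal(vb_update_delta(1, 1, 1, 1, 1), 3)
  expect_equal(vb_update_eta(1, rep(1, 2), rep(0, 2), rep(0, 2), 5), 5)
  set.seed(11)
  a <- runif(1, 0.5, 2); g <- runif(1, 0.5, 2)
  mu <- rnorm(4); Sd <- runif(4)
  expect_equal(vb_update_delta(a, g, mu, Sd, 1.5),
               a * g * (mu^2 + Sd) + 1.5)
  b <- runif(4, 0.2, 3)
  expect_equal(vb_update_eta(a, b, mu, Sd, 0.7),
               a * sum(b * (mu^2 + Sd)) + 0.7)
  expect_gt(min(vb_update_delta(a, g, mu, Sd, 1.5)), 1.5)
  expect_gt(vb_update_eta(a, b, mu, Sd, 0.7), 0.7)
})

test_that("noise-scale update reproduces hand-computed cases", {
  # degenerate: zero coefficients leave half the response sum of squares
  y <- c(1, 2, 3)
  X <- matrix(rnorm(6), 3, 2)
  z0 <- vb_update_zeta(X, y, rep(0, 2), matrix(0, 2, 2), g = 1, b = rep(1, 2))
  expect_equal(z0, sum(y^2) / 2)
  # scalar arithmetic case
  z1 <- vb_update_zeta(matrix(1), 2, 1, matrix(1 / 2), g = 1, b = 1)
  expect_equal(z1, 3 / 2)
  # random instance against direct recomputation
  set.seed(21)
  X <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8)
  mu <- rnorm(3); S <- crossprod(matrix(rnorm(9), 3)); b <- runif(3); g <- 1.4
  direct <- 0.5 * (sum(y^2) - 2 * sum(y * X %*% mu) +
                     sum(diag(crossprod(X) %*% S)) +
                     drop(t(mu) %*% crossprod(X) %*% mu) +
                     g * sum(diag(diag(b) %*% S)) + g * sum(b * mu^2))
  expect_equal(vb_update_zeta(X, y, mu, S, g, b), direct, tolerance = 1e-12)
})

test_that("posterior expectations equal the GIG moments of the factors", {
  ex <- vb_expectations(zeta = 1.5, delta = 1, eta = 2, phi = 1, chi = 1,
                        lambda_feat = 1, lambda_drug = 1, n = 1, p = 1)
  expect_equal(ex$a, 1)
  # b = E[1/gamma2] under GIG(-1, 1, 1)
  expect_equal(ex$b, quad_gig_moment(-1, 1, 1, -1), tolerance = 1e-8)
  expect_equal(ex$b, 2.69947, tolerance = 1e-5)
  # e = E[gamma2] under the same factor
  expect_equal(ex$e, quad_gig_moment(-1, 1, 1, 1), tolerance = 1e-8)
  # g and f are the GIG(-(p+1)/2, ...) moments
  p <- 7
  ex2 <- vb_expectations(1, delta = rep(1, p), eta = 3, phi = 1, chi = 0.5,
                         lambda_feat = 2, lambda_drug = 1.2, n = 10, p = p)
  expect_equal(ex2$g, quad_gig_moment(-(p + 1) / 2, 1.2 / 0.25, 3, -1),
               tolerance = 1e-8)
  expect_equal(ex2$f, quad_gig_moment(-(p + 1) / 2, 1.2 / 0.25, 3, 1),
               tolerance = 1e-8)
  # Cauchy-Schwarz pairs
  expect_true(all(ex2$e * ex2$b >= 1))
  expect_gte(ex2$f * ex2$g, 1)
})

test_that("the variational fit reaches a fixed point of its own updates", {
  toy <- toy_regression(n = 30, p = 5)
  fit <- nig_vb(toy$X, toy$y, phi = 1, chi = 1, lambda_feat = 1,
                lambda_drug = 1, tol = 1e-10, keep_cov = TRUE)
  expect_true(fit$converged)
  # one further full cycle must leave the state essentially unchanged
  up <- vb_update_beta(toy$X, toy$y, fit$a, fit$b, fit$g)
  expect_lt(max(abs(up$mean - fit$mu)), 1e-8)
  delta2 <- vb_update_delta(fit$a, fit$g, up$mean, diag(up$cov),
                            fit$lambda_feat)
  expect_equal(delta2, fit$delta, tolerance = 1e-6)
  ex <- vb_expectations(fit$zeta, fit$delta, fit$eta, fit$phi, fit$chi,
                        fit$lambda_feat, fit$lambda_drug, fit$n, fit$p)
  expect_equal(ex$b, fit$b, tolerance = 1e-6)
  expect_equal(ex$g, fit$g, tolerance = 1e-6)
  expect_equal(ex$a, fit$a, tolerance = 1e-6)
  # state invariants
  expect_true(all(fit$delta > fit$lambda_feat))
  expect_gt(fit$eta, fit$lambda_drug)
  expect_gt(fit$zeta, 0)
  expect_true(all(fit$e * fit$b >= 1))
  expect_gte(fit$f * fit$g, 1)
})

test_that("normal-means posterior contracts every observation towards zero", {
  # identity design, noise and global scales pinned at one
  p <- 12
  set.seed(5)
  y <- rnorm(p, sd = 2)
  fit <- nig_vb(diag(p), y, phi = 1, chi = 1, lambda_feat = 1,
                lambda_drug = 1, a_fixed = 1, g_fixed = 1)
  ratio <- fit$mu / y
  expect_true(all(ratio > 0 & ratio < 1))
})

test_that("large shape parameters collapse the fit to ridge regression", {
  toy <- toy_regression(n = 25, p = 4)
  cphi <- 0.5; cchi <- 2
  fit <- nig_vb(toy$X, toy$y, phi = cphi, chi = cchi,
                lambda_feat = 1e10, lambda_drug = 1e10, tol = 1e-10)
  ridge <- drop(solve(crossprod(toy$X) + diag(1 / (cphi * cchi), 4),
                      crossprod(toy$X, toy$y)))
  expect_equal(fit$mu, ridge, tolerance = 1e-4)
})

test_that("feature permutation permutes the reported posterior identically", {
  toy <- toy_regression(n = 30, p = 6)
  phi <- c(1, 0.5, 0.25, 1, 2, 0.125)
  fit <- nig_vb(toy$X, toy$y, phi = phi, chi = 1, lambda_feat = 1,
                lambda_drug = 1)
  perm <- c(3, 1, 6, 2, 5, 4)
  fit_p <- nig_vb(toy$X[, perm], toy$y, phi = phi[perm], chi = 1,
                  lambda_feat = 1, lambda_drug = 1)
  expect_equal(fit_p$mu, fit$mu[perm], tolerance = 1e-8)
  expect_equal(fit_p$Sigma_diag, fit$Sigma_diag[perm], tolerance = 1e-8)
})

test_that("dual-system (Woodbury) solver agrees with the dense solver", {
  set.seed(9)
  n <- 20; p <- 60
  X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  beta <- c(rep(1.5, 3), rep(0, p - 3))
  y <- drop(X %*% beta) + rnorm(n)
  y <- y - mean(y)
  fd <- nig_vb(X, y, phi = 0.5, chi = 1, lambda_feat = 1, lambda_drug = 1,
               method = "dense", tol = 1e-9)
  fw <- nig_vb(X, y, phi = 0.5, chi = 1, lambda_feat = 1, lambda_drug = 1,
               method = "woodbury", tol = 1e-9)
  expect_equal(fw$mu, fd$mu, tolerance = 1e-7)
  expect_equal(fw$Sigma_diag, fd$Sigma_diag, tolerance = 1e-7)
  expect_equal(fw$zeta, fd$zeta, tolerance = 1e-7)
})

test_that("degenerate inputs are rejected with clear errors", {
  toy <- toy_regression(n = 20, p = 3)
  Xc <- cbind(toy$X, 0)  # constant column
  expect_error(nig_vb(Xc, toy$y, 1, 1, 1, 1), "zero-variance")
  expect_error(nig_vb(toy$X, c(toy$y[-1], NA), 1, 1, 1, 1), "missing")
  expect_error(nig_vb(toy$X, toy$y, -1, 1, 1, 1))
  # non-convergence carries an iteration trace
  err <- tryCatch(nig_vb(toy$X, toy$y, 1, 1, 1, 1, tol = 0, max_iter = 3L),
                  error = function(e) e)
  expect_match(conditionMessage(err), "did not converge")
})

test_that("unpenalized covariates are fit without shrinkage", {
  set.seed(14)
  n <- 60
  X <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
  U <- cbind(rep(c(0, 1), each = n / 2))  # tissue-style indicator
  y <- drop(X %*% c(1, 0, 0)) + 3 * U[, 1] + rnorm(n, sd = 0.3)
  y <- y - mean(y)
  fit <- nig_vb(X, y, phi = 1, chi = 1, lambda_feat = 1, lambda_drug = 1,
                unpenalized = U)
  expect_length(fit$mu_unpenalized, 1)
  # flat-prior coefficient stays near its least-squares value
  ls <- coef(lm(y ~ cbind(X, U) - 1))
  expect_equal(fit$mu_unpenalized, unname(ls[4]), tolerance = 0.05)
  expect_length(fit$delta, 3)  # unpenalized column excluded from shrinkage
})
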