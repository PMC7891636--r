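#' @name vb_updates
#' @title Variational coordinate-ascent updates for one drug
#'
#' @description
#' The per-drug posterior is approximated by a mean-field factorisation
#' \eqn{q(\beta)\,q(\gamma^2)\,q(\tau^2)\,q(\sigma^2)} whose optimal factors
#' are Gaussian, per-coordinate GIG, GIG, and inverse gamma respectively.
#' These helpers perform one coordinate update each; [nig_vb()] cycles them
#' to convergence.  They operate on dense inputs and exist mainly so that
#' each algebraic step can be tested against direct recomputation; the
#' fitting loop uses an internal fused version with precomputed
#' cross-products.
#'
#' Notation: `a`, `b`, `g` are the current posterior expectations of
#' \eqn{1/\sigma^2}, \eqn{1/\gamma_j^2} and \eqn{1/\tau^2}; `mu`/`Sigma` the
#' Gaussian factor's mean and covariance; `delta`, `eta`, `zeta` the data
#' dependent parameters of the \eqn{\gamma_j^2}, \eqn{\tau^2} and
#' \eqn{\sigma^2} factors.
NULL

#' @rdname vb_updates
#' @param X Design matrix (n x p), columns centred.
#' @param y Centred response vector, length n.
#' @param a Posterior expectation of the error precision.
#' @param b Vector of posterior expectations of the local precisions.
#' @param g Posterior expectation of the global precision.
#' @return `vb_update_beta`: list with `mean` (length p) and `cov` (p x p).
#' @export
vb_update_beta <- function(X, y, a, b, g) {
  p <- ncol(X)
  stopifnot(length(b) == p, all(b > 0), a > 0, g > 0)
  A <- crossprod(X)
  diag(A) <- diag(A) + g * b
  R <- tryCatch(chol(A), error = function(e)
    stop("singular system in coefficient update: ", conditionMessage(e)))
  Ainv <- chol2inv(R)
  list(mean = drop(Ainv %*% crossprod(X, y)), cov = Ainv / a)
}

#' @rdname vb_updates
#' @param mu Current posterior mean of the coefficients.
#' @param Sigma_diag Diagonal of the posterior coefficient covariance.
#' @param lambda_feat Feature-level shape parameter.
#' @return `vb_update_delta`: vector \eqn{\delta_j = a g (\mu_j^2 +
#'   \Sigma_{jj}) + \lambda_{feat}}, each entry above `lambda_feat`.
#' @export
vb_update_delta <- function(a, g, mu, Sigma_diag, lambda_feat) {
  a * g * (mu^2 + Sigma_diag) + lambda_feat
}

#' @rdname vb_updates
#' @param lambda_drug Drug-level shape parameter.
#' @return `vb_update_eta`: scalar \eqn{\eta = a \sum_j b_j (\mu_j^2 +
#'   \Sigma_{jj}) + \lambda_{drug}}.
#' @export
vb_update_eta <- function(a, b, mu, Sigma_diag, lambda_drug) {
  a * sum(b * (mu^2 + Sigma_diag)) + lambda_drug
}

#' @rdname vb_updates
#' @param Sigma Posterior coefficient covariance (p x p).
#' @return `vb_update_zeta`: scalar
#'   \eqn{\zeta = \frac12[y'y - 2 y'X\mu + tr(X'X\Sigma) + \mu'X'X\mu +
#'   g\,tr(diag(b)\Sigma) + g\,\mu'diag(b)\mu]}.
#' @export
vb_update_zeta <- function(X, y, mu, Sigma, g, b) {
  xtx <- crossprod(X)
  z <- 0.5 * (sum(y^2) - 2 * sum(y * (X %*% mu)) +
                sum(xtx * Sigma) + drop(crossprod(mu, xtx %*% mu)) +
                g * sum(b * diag(Sigma)) + g * sum(b * mu^2))
  if (z <= 0) stop("nonpositive zeta: numerical failure in noise update")
  z
}

#' @rdname vb_updates
#' @param zeta Current \eqn{\sigma^2}-factor parameter.
#' @param delta Current \eqn{\gamma_j^2}-factor parameters (length p).
#' @param eta Current \eqn{\tau^2}-factor parameter.
#' @param phi Feature-level prior means (length p).
#' @param chi Drug-level prior mean (scalar).
#' @param n,p Sample size and number of penalized features.
#' @return `vb_expectations`: list with elements
#'   `a` \eqn{= E(1/\sigma^2) = (n + p + 1)/(2\zeta)},
#'   `b` \eqn{= E(1/\gamma_j^2)}, `g` \eqn{= E(1/\tau^2)},
#'   `e` \eqn{= E(\gamma_j^2)} and `f` \eqn{= E(\tau^2)}, the GIG moments
#'   expressed through Bessel ratios.
#' @export
vb_expectations <- function(zeta, delta, eta, phi, chi,
                            lambda_feat, lambda_drug, n, p) {
  a <- (n + p + 1) / (2 * zeta)
  nu_f <- lambda_feat / phi^2
  s <- sqrt(delta * nu_f)
  ratio_f <- vapply(s, function(si) .bk_ratio1(0, si), numeric(1))
  b <- sqrt(nu_f / delta) * ratio_f + 2 / delta
  nu_d <- lambda_drug / chi^2
  t <- sqrt(eta * nu_d)
  ratio_d <- .bk_ratio1((p - 1) / 2, t)
  g <- sqrt(nu_d / eta) * ratio_d + (p + 1) / eta
  e <- (b - 2 / delta) * delta * phi^2 / lambda_feat
  f <- (g - (p + 1) / eta) * eta * chi^2 / lambda_drug
  if (!all(is.finite(c(a, b, g, e, f))))
    stop("non-finite posterior expectation: numerical failure")
  list(a = a, b = b, g = g, e = e, f = f)
}

#' Variational Bayes fit of the NIG model for a single response
#'
#' Runs the coordinate-ascent updates for one drug until the posterior mean
#' of the coefficients stabilises.  The prior is
#' \eqn{\beta_j \sim N(0, \gamma_j^2 \tau^2 \sigma^2)} with
#' \eqn{\gamma_j^2 \sim IG(\phi_j, \lambda_{feat})},
#' \eqn{\tau^2 \sim IG(\chi, \lambda_{drug})} and Jeffreys prior
#' \eqn{1/\sigma^3} on the noise scale.
#'
#' @param X Centred design matrix (n x p).
#' @param y Centred response vector (length n).
#' @param phi Feature-level prior means, scalar or length-p vector.
#' @param chi Drug-level prior mean (scalar).
#' @param lambda_feat,lambda_drug Positive shape parameters of the two
#'   inverse Gaussian mixing priors.
#' @param unpenalized Optional n x u matrix of covariates whose coefficients
#'   get a flat prior (no shrinkage); they are excluded from all variance
#'   component updates.
#' @param tol Convergence tolerance: maximum absolute change of the
#'   coefficient posterior mean plus relative change of `zeta` and `eta`.
#' @param max_iter Iteration cap; exceeding it is an error (the trace so far
#'   is attached to the condition).
#' @param a_fixed,g_fixed Optionally pin the posterior expectations of
#'   \eqn{1/\sigma^2} resp. \eqn{1/\tau^2} at a known value (used for
#'   degenerate-limit checks such as the normal-means model).
#' @param init Optional warm start: a previous `"nig_vb"` state whose
#'   `b`, `g`, `a` seed the first update.
#' @param method Linear-algebra route for the coefficient update: `"dense"`
#'   factorises the p x p system, `"woodbury"` solves the n x n dual system
#'   (cost O(n^2 p), preferable when p >> n), `"auto"` picks by shape.
#' @param keep_cov Return the full posterior covariance matrix? (It is
#'   always available implicitly; storing it is O(p^2).)
#' @param xtx Optional precomputed `crossprod(X)` (dense method only);
#'   lets a multi-drug driver share the Gram matrix across drugs.
#' @param check Validate inputs (missingness, constant columns)?  Drivers
#'   that have already validated may disable this.
#' @return An object of class `"nig_vb"`: list with `mu`, `Sigma_diag`,
#'   optionally `Sigma`, `delta`, `eta`, `zeta`, expectations `a`, `b`, `g`,
#'   `e`, `f`, the prior used, `iterations` and `converged`.
#' @examples
#' set.seed(1)
#' X <- scale(matrix(rnorm(40), 10, 4), scale = FALSE)
#' y <- drop(X %*% c(1, -1, 0, 0)) + rnorm(10, sd = 0.5)
#' fit <- nig_vb(X, y - mean(y), phi = 1, chi = 1,
#'               lambda_feat = 1, lambda_drug = 1)
#' fit$mu
#' @export
nig_vb <- function(X, y, phi, chi, lambda_feat, lambda_drug,
                   unpenalized = NULL, tol = 1e-6, max_iter = 1000L,
                   a_fixed = NULL, g_fixed = NULL, init = NULL,
                   method = c("auto", "dense", "woodbury"),
                   keep_cov = FALSE, xtx = NULL, check = TRUE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n, p >= 1L)
  if (check) {
    if (anyNA(X) || anyNA(y)) stop("missing values must be removed per drug")
    csd <- colMeans(X^2) - colMeans(X)^2
    if (any(csd <= 0))
      stop("zero-variance feature column(s): ",
           paste(utils::head(which(csd <= 0), 5L), collapse = ", "),
           " (centred constant columns make the system singular)")
  }
  phi <- rep_len(phi, p)
  stopifnot(all(phi > 0), chi > 0, lambda_feat > 0, lambda_drug > 0)
  if (!is.null(unpenalized)) {
    unpenalized <- as.matrix(unpenalized)
    stopifnot(nrow(unpenalized) == n)
    if (method == "woodbury")
      stop("unpenalized covariates require the dense solver")
    method <- "dense"
  }
  u <- if (is.null(unpenalized)) 0L else ncol(unpenalized)
  Xa <- if (u) cbind(X, unpenalized) else X
  pen <- seq_len(p)
  if (method == "auto") method <- if (p > 1.5 * n && p > 200L) "woodbury" else "dense"

  if (method == "dense" && is.null(xtx)) xtx <- crossprod(Xa)
  xty <- crossprod(Xa, y)
  yty <- sum(y^2)

  # init: expectation-consistent with the prior means
  if (!is.null(init) && inherits(init, "nig_vb") && length(init$b) == p) {
    b <- init$b; g <- init$g; a <- init$a
  } else {
    b <- 1 / phi
    g <- 1 / chi
    a <- 1
  }
  if (!is.null(g_fixed)) g <- g_fixed
  if (!is.null(a_fixed)) a <- a_fixed

  mu_old <- rep(Inf, p + u)
  zeta_old <- eta_old <- Inf
  converged <- FALSE
  trace <- numeric(0)
  nu_f <- lambda_feat / phi^2
  sqrt_nu_f <- sqrt(nu_f)
  nu_d <- lambda_drug / chi^2

  for (iter in seq_len(max_iter)) {
    d_all <- c(g * b, rep(0, u))  # flat prior: zero precision contribution
    if (method == "dense") {
      A <- xtx
      diag(A) <- diag(A) + d_all
      Ainv <- chol2inv(chol(A))
      Ainv_diag <- diag(Ainv)
      mu <- drop(Ainv %*% xty)
      # tr(X'X A^-1) = (p+u) - sum(d * diag(A^-1))
      tr_xtx_Ainv <- (p + u) - sum(d_all * Ainv_diag)
      quad_xtx_mu <- drop(crossprod(mu, xtx %*% mu))
    } else {
      wd <- .woodbury_solve(Xa, xty, d_all)
      mu <- wd$mu
      Ainv_diag <- wd$Ainv_diag
      tr_xtx_Ainv <- p + u - sum(d_all * Ainv_diag)
      quad_xtx_mu <- sum((Xa %*% mu)^2)
    }
    mu_pen <- mu[pen]
    Sjj <- Ainv_diag / a        # diag of Sigma = A^-1 / a
    Sjj_pen <- Sjj[pen]

    delta <- vb_update_delta(a, g, mu_pen, Sjj_pen, lambda_feat)
    sarg <- sqrt(delta) * sqrt_nu_f
    # order-0 ratio K_0/K_1 vectorises directly over the scaled arguments
    b_new <- sqrt_nu_f / sqrt(delta) *
      (besselK(sarg, 0, expon.scaled = TRUE) /
         besselK(sarg, 1, expon.scaled = TRUE)) + 2 / delta

    eta <- vb_update_eta(a, b_new, mu_pen, Sjj_pen, lambda_drug)
    if (is.null(g_fixed)) {
      targ <- sqrt(eta * nu_d)
      g_new <- sqrt(nu_d / eta) * .bk_ratio1((p - 1) / 2, targ) + (p + 1) / eta
    } else g_new <- g_fixed

    zeta <- 0.5 * (yty - 2 * sum(xty * mu) + tr_xtx_Ainv / a + quad_xtx_mu +
                     g_new * (sum(b_new * Sjj_pen) + sum(b_new * mu_pen^2)))
    if (zeta <= 0) stop("nonpositive zeta: numerical failure in noise update")
    a_new <- if (is.null(a_fixed)) (n + p + 1) / (2 * zeta) else a_fixed

    eps <- max(abs(mu - mu_old))
    rel <- max(abs(zeta - zeta_old) / zeta, abs(eta - eta_old) / eta)
    trace[iter] <- eps
    b <- b_new; g <- g_new; a <- a_new
    mu_old <- mu; zeta_old <- zeta; eta_old <- eta
    if (eps < tol && rel < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "variational fit did not converge in %d iterations (last max |d mu| = %.3g)",
      max_iter, trace[length(trace)]))
    cond$trace <- trace
    stop(cond)
  }

  e <- (b - 2 / delta) * delta * phi^2 / lambda_feat
  f <- if (is.null(g_fixed))
    (g - (p + 1) / eta) * eta * chi^2 / lambda_drug
  else 1 / g_fixed

  out <- list(mu = mu_pen, mu_unpenalized = if (u) mu[-pen] else NULL,
              Sigma_diag = Sjj_pen, delta = delta, eta = eta, zeta = zeta,
              a = a, b = b, g = g, e = e, f = f,
              phi = phi, chi = chi,
              lambda_feat = lambda_feat, lambda_drug = lambda_drug,
              n = n, p = p, iterations = iter, converged = converged,
              trace = trace)
  if (keep_cov) {
    if (method == "dense") {
      out$Sigma <- Ainv / a
    } else {
      A <- crossprod(Xa)
      diag(A) <- diag(A) + d_all
      out$Sigma <- chol2inv(chol(A)) / a
    }
  }
  class(out) <- "nig_vb"
  out
}

#' @export
print.nig_vb <- function(x, ...) {
  cat(sprintf("NIG variational fit: n = %d, p = %d, %d iterations\n",
              x$n, x$p, x$iterations))
  cat(sprintf("  E(sigma^2) approx %.4g, E(tau^2) = %.4g\n",
              x$zeta / ((x$n + x$p + 1) / 2 - 1), x$f))
  invisible(x)
}

# Solve (X'X + diag(d)) m = xty and get diag((X'X + diag(d))^-1)
# through the n x n dual system; requires all d > 0.
.woodbury_solve <- function(X, xty, d) {
  n <- nrow(X)
  Xd <- sweep(X, 2L, d, "/")         # X D^-1
  M <- diag(n) + tcrossprod(Xd, X)   # I + X D^-1 X'
  R <- chol(M)
  rhs <- X %*% (xty / d)
  Minv_rhs <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  mu <- drop(xty / d - crossprod(Xd, Minv_rhs))
  # diag(A^-1)_j = 1/d_j - (1/d_j^2) x_j' M^-1 x_j
  W <- backsolve(R, backsolve(R, X, transpose = TRUE))
  Ainv_diag <- 1 / d - colSums(X * W) / d^2
  list(mu = mu, Ainv_diag = Ainv_diag)
}
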