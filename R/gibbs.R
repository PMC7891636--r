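#' Gibbs sampler for the NIG regression posterior (fixed hyperparameters)
#'
#' Samples the exact per-drug posterior of the NIG shrinkage model by Gibbs
#' sampling, as an independent check on the variational approximation.  All
#' full conditionals follow from conjugacy:
#' \describe{
#'   \item{coefficients}{\eqn{\beta | \cdot \sim N(m, V)} with
#'     \eqn{V = \sigma^2 (X'X + diag(1/(\gamma_j^2\tau^2)))^{-1}} and
#'     \eqn{m = (X'X + diag(1/(\gamma_j^2\tau^2)))^{-1} X'y},}
#'   \item{local components}{\eqn{\gamma_j^2 | \cdot \sim
#'     GIG(-1,\ \lambda_{feat}/\phi_j^2,\ \lambda_{feat} +
#'     \beta_j^2/(\tau^2\sigma^2))},}
#'   \item{global component}{\eqn{\tau^2 | \cdot \sim
#'     GIG(-(p+1)/2,\ \lambda_{drug}/\chi^2,\ \lambda_{drug} +
#'     \sum_j \beta_j^2/(\gamma_j^2\sigma^2))},}
#'   \item{noise}{\eqn{\sigma^2 | \cdot \sim}
#'     inverse-gamma\eqn{((n+p+1)/2,\ \frac12[\|y - X\beta\|^2 +
#'     \sum_j \beta_j^2/(\gamma_j^2\tau^2)])}.}
#' }
#' The GIG draws use the log-concave rejection sampler in [rgig()].
#'
#' @inheritParams nig_vb
#' @param n_iter Total iterations (default 10000).
#' @param burn_in Discarded initial iterations (default 2000).
#' @param seed Optional integer seed fixing the chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @return Object of class `"nig_gibbs"`: list with matrices `beta`
#'   (draws x p), `gamma2` (draws x p), vectors `tau2`, `sigma2`, and the
#'   dimensions.
#' @examples
#' set.seed(3)
#' X <- scale(matrix(rnorm(60), 20, 3), scale = FALSE)
#' y <- drop(X %*% c(1, 0, -1)) + rnorm(20)
#' ch <- nig_gibbs(X, y - mean(y), phi = 1, chi = 1, lambda_feat = 1,
#'                 lambda_drug = 1, n_iter = 500, burn_in = 100, seed = 1)
#' colMeans(ch$beta)
#' @export
nig_gibbs <- function(X, y, phi, chi, lambda_feat, lambda_drug,
                      n_iter = 10000L, burn_in = 2000L, seed = NULL,
                      thin = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n_iter > burn_in, thin >= 1L)
  phi <- rep_len(phi, p)
  stopifnot(all(phi > 0), chi > 0, lambda_feat > 0, lambda_drug > 0)
  if (!is.null(seed)) set.seed(seed)

  xtx <- crossprod(X)
  xty <- drop(crossprod(X, y))

  # initial values at the prior means
  gamma2 <- phi
  tau2 <- chi
  sigma2 <- 1

  keep <- seq(burn_in + 1L, n_iter, by = thin)
  beta_out <- matrix(NA_real_, length(keep), p)
  gamma2_out <- matrix(NA_real_, length(keep), p)
  tau2_out <- sigma2_out <- numeric(length(keep))
  k <- 0L

  nu_gamma <- lambda_feat / phi^2
  nu_tau <- lambda_drug / chi^2

  for (it in seq_len(n_iter)) {
    prec_prior <- 1 / (gamma2 * tau2)
    A <- xtx
    diag(A) <- diag(A) + prec_prior
    R <- chol(A)
    m <- backsolve(R, backsolve(R, xty, transpose = TRUE))
    # beta = m + sqrt(sigma2) * R^-1 z, since V = sigma2 * A^-1 = sigma2 R^-1 R^-T
    beta <- drop(m + sqrt(sigma2) * backsolve(R, stats::rnorm(p)))

    for (j in seq_len(p))
      gamma2[j] <- .rgig1(-1, nu_gamma[j],
                          lambda_feat + beta[j]^2 / (tau2 * sigma2))
    tau2 <- .rgig1(-(p + 1) / 2, nu_tau,
                   lambda_drug + sum(beta^2 / gamma2) / sigma2)
    resid <- y - drop(X %*% beta)
    rate <- 0.5 * (sum(resid^2) + sum(beta^2 / gamma2) / tau2)
    sigma2 <- 1 / stats::rgamma(1L, shape = (n + p + 1) / 2, rate = rate)

    if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
      k <- k + 1L
      beta_out[k, ] <- beta
      gamma2_out[k, ] <- gamma2
      tau2_out[k] <- tau2
      sigma2_out[k] <- sigma2
    }
  }
  structure(list(beta = beta_out, gamma2 = gamma2_out, tau2 = tau2_out,
                 sigma2 = sigma2_out, n = n, p = p, n_iter = n_iter,
                 burn_in = burn_in, thin = thin),
            class = "nig_gibbs")
}

#' @export
print.nig_gibbs <- function(x, ...) {
  cat(sprintf(
    "NIG Gibbs chain: %d kept draws (n_iter %d, burn-in %d), n = %d, p = %d\n",
    nrow(x$beta), x$n_iter, x$burn_in, x$n, x$p))
  invisible(x)
}

#' Monte Carlo standard error by batch means
#'
#' Standard error of a chain mean that accounts for autocorrelation by the
#' non-overlapping batch-means estimator.
#'
#' @param x Numeric vector (one chain).
#' @param n_batches Number of batches (default 30).
#' @return Estimated standard error of `mean(x)`.
#' @export
mcse <- function(x, n_batches = 30L) {
  m <- length(x) %/% n_batches
  stopifnot(m >= 2L)
  means <- colMeans(matrix(x[seq_len(m * n_batches)], m, n_batches))
  stats::sd(means) / sqrt(n_batches)
}

#' Export a Gibbs chain as delimited text
#'
#' Writes kept draws (one row per draw; columns `beta.1..p`, `gamma2.1..p`,
#' `tau2`, `sigma2`) to a tab-separated file for external diagnostics.
#'
#' @param chain A `"nig_gibbs"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "nig_gibbs"))
  tab <- cbind(chain$beta, chain$gamma2, chain$tau2, chain$sigma2)
  colnames(tab) <- c(paste0("beta.", seq_len(chain$p)),
                     paste0("gamma2.", seq_len(chain$p)), "tau2", "sigma2")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
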