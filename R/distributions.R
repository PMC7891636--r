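#' Inverse Gaussian density
#'
#' Density of the inverse Gaussian distribution \eqn{IG(\phi, \lambda)}
#' parameterised by its mean \eqn{\phi > 0} and shape \eqn{\lambda > 0},
#' \deqn{f(x) = \sqrt{\lambda / (2\pi x^3)}\,
#'   \exp\{-\lambda (x - \phi)^2 / (2 \phi^2 x)\}, \quad x > 0.}
#' This is the mixing distribution of the variance components in the NIG
#' prior: a normal coefficient whose variance is IG-distributed has a normal
#' inverse Gaussian marginal.
#'
#' @param x Vector of positive evaluation points.
#' @param mean Prior mean \eqn{\phi > 0}.
#' @param shape Shape \eqn{\lambda > 0}; larger values concentrate the
#'   distribution around `mean`.
#' @param log Return the log density?
#' @return Numeric vector of (log) density values.
#' @seealso [dgig()] for the conjugate posterior family, [dkappa_nig()] for
#'   the implied shrinkage-weight density.
#' @examples
#' dinvgauss(1, mean = 1, shape = 1)  # 1/sqrt(2*pi)
#' @export
dinvgauss <- function(x, mean, shape, log = FALSE) {
  stopifnot(all(x > 0), all(mean > 0), all(shape > 0))
  ld <- 0.5 * (base::log(shape) - base::log(2 * pi) - 3 * base::log(x)) -
    shape * (x - mean)^2 / (2 * mean^2 * x)
  if (log) ld else exp(ld)
}

#' Inverse Gaussian random variates
#'
#' Generates draws from \eqn{IG(\phi, \lambda)} by the transformation method
#' of Michael, Schucany and Haas (1976).
#'
#' @param n Number of draws.
#' @param mean Mean \eqn{\phi > 0} (recycled).
#' @param shape Shape \eqn{\lambda > 0} (recycled).
#' @return Numeric vector of length `n`.
#' @export
rinvgauss <- function(n, mean, shape) {
  stopifnot(all(mean > 0), all(shape > 0))
  mean <- rep_len(mean, n)
  shape <- rep_len(shape, n)
  y <- stats::rnorm(n)^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Generalized inverse Gaussian parameter set
#'
#' Constructs a GIG parameter object for the convention used throughout the
#' package: \eqn{GIG(p, \nu, \eta)} has density
#' \deqn{f(x) \propto x^{p - 1} \exp\{-(\nu x + \eta / x)/2\}, \quad x > 0,}
#' with index \eqn{p \in R}, `coef_x` \eqn{= \nu > 0} multiplying \eqn{x} and
#' `coef_invx` \eqn{= \eta > 0} multiplying \eqn{1/x}.  This is the
#' variational posterior family of the NIG variance components.
#'
#' @param index Real index \eqn{p}.
#' @param coef_x Positive coefficient of \eqn{x} in the exponent.
#' @param coef_invx Positive coefficient of \eqn{1/x} in the exponent.
#' @return An object of class `"gig"`.
#' @export
gig <- function(index, coef_x, coef_invx) {
  stopifnot(is.numeric(index), length(index) == 1L, is.finite(index))
  if (!(coef_x > 0) || !(coef_invx > 0))
    stop("'coef_x' and 'coef_invx' must be strictly positive")
  structure(list(index = index, coef_x = coef_x, coef_invx = coef_invx),
            class = "gig")
}

#' @export
print.gig <- function(x, ...) {
  cat(sprintf("GIG(index = %g, coef_x = %g, coef_invx = %g)\n",
              x$index, x$coef_x, x$coef_invx))
  invisible(x)
}

#' Represent an inverse Gaussian distribution as a GIG
#'
#' Completing the square in the IG exponent shows that
#' \eqn{IG(\phi, \lambda) = GIG(-1/2, \lambda / \phi^2, \lambda)} (a constant
#' factor \eqn{e^{\lambda/\phi}} is absorbed in the normalisation).
#'
#' @param mean IG mean \eqn{\phi > 0}.
#' @param shape IG shape \eqn{\lambda > 0}.
#' @return A `"gig"` object.
#' @examples
#' ig_to_gig(1, 1)  # GIG(-1/2, 1, 1)
#' @export
ig_to_gig <- function(mean, shape) {
  stopifnot(mean > 0, shape > 0)
  gig(index = -1 / 2, coef_x = shape / mean^2, coef_invx = shape)
}

#' Ratio of modified Bessel functions of the second kind
#'
#' Computes \eqn{K_{\nu}(x) / K_{\nu + 1}(x)} without overflow for large
#' arguments or orders.  Exponentially scaled Bessel functions are used for
#' the fractional starting order, so the \eqn{e^{-x}} factors cancel
#' analytically; larger orders are reached through the upward recurrence
#' \eqn{K_{\nu+1}(x) = K_{\nu-1}(x) + (2\nu/x) K_\nu(x)} applied to the
#' ratio sequence, which is stable because the ratios grow monotonically.
#' Half-integer orders start from the closed form
#' \eqn{K_{3/2}(x)/K_{1/2}(x) = 1 + 1/x}.
#'
#' The variational update for the global variance component needs this ratio
#' at order \eqn{(p+1)/2} where \eqn{p} is the number of features, so the
#' routine must remain finite for orders in the tens of thousands, where the
#' scaled Bessel routines themselves overflow.
#'
#' @param order Real order \eqn{\nu}; the ratio returned is
#'   \eqn{K_{order}/K_{order+1}}.
#' @param arg Positive argument, possibly vector.
#' @return Numeric vector of ratios; lies in \eqn{(0, 1]} for
#'   `order >= -1/2`.
#' @examples
#' besselK_ratio(1/2, 2)  # 2/3 exactly
#' @export
besselK_ratio <- function(order, arg) {
  stopifnot(length(order) == 1L, is.finite(order))
  if (any(arg <= 0)) stop("'arg' must be strictly positive")
  vapply(arg, function(x) .bk_ratio1(order, x), numeric(1))
}

# K_order(x)/K_{order+1}(x) for scalar order and x.
.bk_ratio1 <- function(order, x) {
  # K_{-nu} = K_nu: reduce to a ratio of nonnegative orders
  lo <- abs(order)
  hi <- abs(order + 1)
  if (hi < lo) return(1 / .bk_ratio1(hi, x))  # e.g. order = -3: K_3/K_2 inverted
  if (abs(hi - lo) < 1e-12) return(1)         # order = -1/2: K_{1/2}/K_{1/2}
  # now hi = lo + 1, lo >= 0; walk r_nu = K_{nu+1}/K_nu up from nu0 in [0, 1)
  nu0 <- lo - floor(lo)
  if (abs(nu0 - 0.5) < 1e-12) {
    r <- 1 + 1 / x                       # K_{3/2}/K_{1/2}, exact
  } else {
    r <- besselK(x, nu0 + 1, expon.scaled = TRUE) /
      besselK(x, nu0, expon.scaled = TRUE)
  }
  nu <- nu0
  steps <- as.integer(round(lo - nu0))
  if (steps > 0) for (k in seq_len(steps)) {
    nu <- nu + 1
    r <- 1 / r + 2 * nu / x
  }
  1 / r
}

#' Moments of the generalized inverse Gaussian distribution
#'
#' Computes \eqn{E[X^k]} for \eqn{X \sim GIG(p, \nu, \eta)} through Bessel
#' function ratios,
#' \deqn{E[X^k] = (\eta/\nu)^{k/2}\, K_{p+k}(\sqrt{\nu\eta}) /
#'   K_p(\sqrt{\nu\eta}),}
#' with the Bessel quotient evaluated as a product of consecutive-order
#' ratios so that it stays finite for extreme parameters.  All integer
#' moments (positive and negative) exist because both exponential
#' coefficients are strictly positive.
#'
#' @param params A `"gig"` object (see [gig()], [ig_to_gig()]).
#' @param power Integer moment order (may be negative).
#' @return The moment \eqn{E[X^{power}]}.
#' @examples
#' gig_moment(ig_to_gig(0.5, 1), 1)    # IG mean: 0.5
#' gig_moment(ig_to_gig(0.5, 1), -1)   # 1/mean + 1/shape: 3
#' @export
gig_moment <- function(params, power) {
  stopifnot(inherits(params, "gig"), length(power) == 1L,
            power == round(power))
  p <- params$index
  nu <- params$coef_x
  eta <- params$coef_invx
  s <- sqrt(nu * eta)
  k <- as.integer(power)
  if (k == 0L) return(1)
  # K_{p+k}/K_p as a telescoping product of K_{m+1}/K_m steps
  log_q <- 0
  if (k > 0L) {
    for (m in p + seq_len(k) - 1) log_q <- log_q - log(.bk_ratio1(m, s))
  } else {
    for (m in p - seq_len(-k)) log_q <- log_q + log(.bk_ratio1(m, s))
  }
  exp(0.5 * k * (log(eta) - log(nu)) + log_q)
}

#' GIG log density
#'
#' Normalised log density of \eqn{GIG(p, \nu, \eta)} (see [gig()] for the
#' convention).  The normalising constant
#' \eqn{2 (\eta/\nu)^{p/2} K_p(\sqrt{\nu\eta})} is evaluated with scaled
#' Bessel functions.  Intended for moderate orders (validation, plotting,
#' quadrature checks); the fitting code itself only ever needs ratios.
#'
#' @inheritParams gig_moment
#' @param x Positive evaluation points.
#' @param log Return the log density?
#' @return Numeric vector.
#' @export
dgig <- function(x, params, log = FALSE) {
  stopifnot(inherits(params, "gig"), all(x > 0))
  p <- params$index
  nu <- params$coef_x
  eta <- params$coef_invx
  s <- sqrt(nu * eta)
  log_norm <- log(2) + 0.5 * p * (log(eta) - log(nu)) +
    log(besselK(s, abs(p), expon.scaled = TRUE)) - s
  ld <- (p - 1) * base::log(x) - (nu * x + eta / x) / 2 - log_norm
  if (log) ld else exp(ld)
}

#' GIG random variates
#'
#' Draws from \eqn{GIG(p, \nu, \eta)} by rejection sampling on the log scale:
#' the density of \eqn{V = \log X} is log-concave for every index, so a
#' piecewise hat (flat around the mode, tangent exponential tails anchored at
#' the points where the log density has dropped by one) dominates it with
#' uniformly bounded rejection rate.  Used by the Gibbs sampler, whose full
#' conditionals for the variance components are GIG.
#'
#' @inheritParams gig_moment
#' @param n Number of draws.
#' @return Numeric vector of positive draws.
#' @export
rgig <- function(n, params) {
  stopifnot(inherits(params, "gig"))
  vapply(seq_len(n), function(i)
    .rgig1(params$index, params$coef_x, params$coef_invx), numeric(1))
}

# single draw from GIG(p, a, b) via log-concave rejection in v = log x
.rgig1 <- function(p, a, b) {
  # mode of h(v) = p v - (a e^v + b e^-v)/2: exp(v*) solves a w^2 - 2p w - b = 0
  w <- (p + sqrt(p^2 + a * b)) / a
  m <- base::log(w)
  hm <- p * m - (a * w + b / w) / 2
  hh <- function(v) p * v - (a * exp(v) + b * exp(-v)) / 2 - hm
  dh <- function(v) p - (a * exp(v) - b * exp(-v)) / 2
  # points where the centred log density drops by 1
  step <- 1
  while (hh(m + step) > -1) step <- step * 2
  vr <- stats::uniroot(function(v) hh(v) + 1, c(m, m + step),
                       tol = 1e-10)$root
  step <- 1
  while (hh(m - step) > -1) step <- step * 2
  vl <- stats::uniroot(function(v) hh(v) + 1, c(m - step, m),
                       tol = 1e-10)$root
  sl <- dh(vl)   # > 0
  sr <- dh(vr)   # < 0
  area <- c(vr - vl, exp(-1) / sl, exp(-1) / (-sr))
  repeat {
    piece <- sample.int(3L, 1L, prob = area)
    if (piece == 1L) {
      v <- stats::runif(1, vl, vr)
      log_hat <- 0
    } else if (piece == 2L) {
      v <- vl + base::log(stats::runif(1)) / sl  # left exponential tail
      log_hat <- -1 + sl * (v - vl)
    } else {
      v <- vr + base::log(stats::runif(1)) / sr  # right tail (sr < 0)
      log_hat <- -1 + sr * (v - vr)
    }
    if (base::log(stats::runif(1)) <= hh(v) - log_hat) return(exp(v))
  }
}

#' Prior moments of an NIG-shrinkage regression coefficient
#'
#' For a coefficient with prior \eqn{\beta | \gamma^2, \tau^2 \sim
#' N(0, \gamma^2 \tau^2)}, \eqn{\gamma^2 \sim IG(\phi, \lambda_f)} and
#' \eqn{\tau^2 \sim IG(\chi, \lambda_d)}, the marginal prior variance is
#' \eqn{V(\beta) = \phi\chi} and the kurtosis is
#' \deqn{K(\beta) = 3\,(1 + \phi/\lambda_f)(1 + \chi/\lambda_d),}
#' from the second moments of the two independent inverse Gaussian mixing
#' distributions.  The multiplicative error-variance factor \eqn{\sigma^2}
#' present in the full prior is excluded, so these are the moments on the
#' standardised coefficient scale.  Kurtosis is always at least 3: the NIG
#' prior is heavier-tailed than the Gaussian (ridge) prior, which is what
#' makes post-hoc selection through [dss_select()] meaningful.
#'
#' @param phi Feature-level (local) prior mean(s) \eqn{\phi > 0}.
#' @param chi Drug-level (global) prior mean(s) \eqn{\chi > 0}.
#' @param lambda_feat Feature-level shape \eqn{\lambda_{feat} > 0}.
#' @param lambda_drug Drug-level shape \eqn{\lambda_{drug} > 0}.
#' @return A list with components `variance` and `kurtosis` (vectorised over
#'   `phi` and `chi`).
#' @examples
#' nig_prior_moments(1, 1, 1, 1)  # variance 1, kurtosis 12
#' @export
nig_prior_moments <- function(phi, chi, lambda_feat, lambda_drug) {
  if (any(phi <= 0) || any(chi <= 0) || lambda_feat <= 0 || lambda_drug <= 0)
    stop("all prior moment arguments must be strictly positive")
  list(variance = phi * chi,
       kurtosis = 3 * (1 + phi / lambda_feat) * (1 + chi / lambda_drug))
}

#' Shrinkage-weight density implied by the inverse Gaussian mixing prior
#'
#' In the normal-means reduction of the model the conditional posterior mean
#' is \eqn{E(\beta | y, \kappa) = (1 - \kappa) y} with shrinkage weight
#' \eqn{\kappa = 1 / (1 + \gamma^2) \in (0, 1)}: \eqn{\kappa = 0} means no
#' shrinkage and \eqn{\kappa = 1} full shrinkage to zero.  This function
#' returns the density of \eqn{\kappa} implied by
#' \eqn{\gamma^2 \sim IG(\phi, \lambda)} through the change of variables
#' \eqn{\gamma^2 = (1 - \kappa)/\kappa} with Jacobian \eqn{1/\kappa^2}.
#' Depending on \eqn{(\phi, \lambda)} the density can place mass near both
#' endpoints, the hallmark of a global-local shrinkage rule.
#'
#' @param kappa Evaluation points strictly inside \eqn{(0, 1)}.
#' @param mean IG mean \eqn{\phi > 0} of the variance component.
#' @param shape IG shape \eqn{\lambda > 0}.
#' @return Numeric vector of density values.
#' @export
dkappa_nig <- function(kappa, mean, shape) {
  if (any(kappa <= 0) || any(kappa >= 1))
    stop("'kappa' must lie strictly inside (0, 1)")
  dinvgauss((1 - kappa) / kappa, mean = mean, shape = shape) / kappa^2
}
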