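#' Empirical Bayes update of the external-covariate coefficients
#'
#' Closed-form M-step for the coefficients linking external covariates to
#' prior precisions.  With `covars` the stacked covariate matrix (intercept
#' first) and `weights_e` the current posterior means of the variance
#' components, the maximiser of the expected complete-data log prior is the
#' weighted least squares solution
#' \deqn{\alpha = (C' diag(e)\, C)^{-1} C' 1.}
#' The same formula serves the feature level (`C`, \eqn{e_{jd}}) and the
#' drug level (`Z`, \eqn{f_d}).  Implied prior means are
#' \eqn{1 / (c'\alpha)}.
#'
#' @param covars Full-column-rank covariate matrix, one row per
#'   feature-drug pair (feature level) or per drug (drug level); first
#'   column is the intercept.
#' @param weights_e Strictly positive vector of posterior mean variance
#'   components, one per row of `covars`.
#' @return Coefficient vector of length `ncol(covars)`.
#' @export
eb_update_alpha <- function(covars, weights_e) {
  covars <- as.matrix(covars)
  stopifnot(nrow(covars) == length(weights_e), all(weights_e > 0))
  A <- crossprod(covars, covars * weights_e)
  R <- tryCatch(chol(A), error = function(err) {
    qr_c <- qr(covars)
    bad <- if (qr_c$rank < ncol(covars))
      paste(colnames(covars)[qr_c$pivot[-seq_len(qr_c$rank)]], collapse = ", ")
    else "unknown"
    stop("external covariate design is rank deficient (collinear columns: ",
         bad, ")")
  })
  drop(backsolve(R, backsolve(R, colSums(covars), transpose = TRUE)))
}

#' Empirical Bayes update of an inverse Gaussian shape parameter
#'
#' Closed-form M-step for the shape \eqn{\lambda} of the inverse Gaussian
#' prior on the variance components:
#' \deqn{\lambda = N \big/ \big(\textstyle\sum b + \alpha' C' diag(e) C
#'   \alpha - 2 \alpha' C' 1\big),}
#' where `b` holds posterior mean precisions and `e` posterior mean variance
#' components.  The denominator is a sum of expected inverse Gaussian
#' deviances and is strictly positive whenever the inputs come from valid
#' posterior expectations (so a nonpositive value signals an inconsistency
#' upstream and is raised as an error rather than clipped).
#'
#' @inheritParams eb_update_alpha
#' @param alpha Current coefficient vector (from [eb_update_alpha()]).
#' @param weights_b Strictly positive posterior mean precisions, same length
#'   as `weights_e`.
#' @param count Number of variance components N (rows of `covars`).
#' @return Strictly positive scalar \eqn{\lambda}.
#' @export
eb_update_lambda <- function(covars, alpha, weights_e, weights_b, count) {
  covars <- as.matrix(covars)
  stopifnot(length(weights_b) == length(weights_e),
            all(weights_b > 0), all(weights_e > 0),
            count == nrow(covars))
  lp <- drop(covars %*% alpha)
  denom <- sum(weights_b) + sum(weights_e * lp^2) - 2 * sum(lp)
  if (denom <= 0)
    stop("nonpositive shape-update denominator (", format(denom),
         "): inconsistent posterior expectations")
  count / denom
}

#' Control parameters for the NIG fit
#'
#' @param tol_vb Inner (per-drug variational) convergence tolerance.
#' @param max_iter_vb Inner iteration cap.
#' @param tol_em Outer relative tolerance on all updated hyperparameters.
#' @param max_iter_em Outer iteration cap.
#' @param update_feature,update_drug Estimate the feature-level resp.
#'   drug-level hyperparameters?  When a level is not updated its prior is
#'   pinned: prior mean `fixed_phi`/`fixed_chi` with a large shape
#'   (`fixed_lambda`), which holds the corresponding variance components
#'   essentially constant.
#' @param use_feature_covars,use_drug_covars Include external covariates at
#'   each level (the "+covariates" model variants)?  With `FALSE` the level
#'   is intercept-only: one common prior mean is estimated.
#' @param fixed_phi,fixed_chi,fixed_lambda Pinning values for levels that
#'   are not updated.
#' @param clip_range Allowed range for implied prior means; linear
#'   predictors whose reciprocal falls outside are clipped (with a warning)
#'   before the next variational pass, keeping the unconstrained closed-form
#'   update intact.
#' @param center_response,center_features Centre responses (per drug) and
#'   feature columns before fitting.  The model assumes centred data.
#' @param scale_response Scale each response to unit variance.  Off by
#'   default for fitting (the model is equivariant to response scale);
#'   cross-validation turns it on so that the empty model has prediction
#'   error one.
#' @param verbose Print per-outer-iteration progress.
#' @return A list of class `"nig_control"`.
#' @export
nig_control <- function(tol_vb = 1e-6, max_iter_vb = 1000L,
                        tol_em = 1e-4, max_iter_em = 100L,
                        update_feature = TRUE, update_drug = TRUE,
                        use_feature_covars = TRUE, use_drug_covars = TRUE,
                        fixed_phi = 1, fixed_chi = 1, fixed_lambda = 1e6,
                        clip_range = c(1e-6, 1e6),
                        center_response = TRUE, center_features = TRUE,
                        scale_response = FALSE, verbose = FALSE) {
  ctrl <- list(tol_vb = tol_vb, max_iter_vb = as.integer(max_iter_vb),
               tol_em = tol_em, max_iter_em = as.integer(max_iter_em),
               update_feature = update_feature, update_drug = update_drug,
               use_feature_covars = use_feature_covars,
               use_drug_covars = use_drug_covars,
               fixed_phi = fixed_phi, fixed_chi = fixed_chi,
               fixed_lambda = fixed_lambda, clip_range = clip_range,
               center_response = center_response,
               center_features = center_features,
               scale_response = scale_response, verbose = verbose)
  class(ctrl) <- "nig_control"
  ctrl
}

#' Fit the NIG shrinkage regression across all drugs
#'
#' Fits the multi-response model
#' \eqn{y_{id} = x_i'\beta_d + \epsilon_{id}} with NIG global-local
#' shrinkage priors by a variational Bayes EM algorithm: the E-step runs
#' per-drug variational coordinate ascent ([nig_vb()]) to convergence, the
#' M-step updates the hyperparameters \eqn{(\alpha_{feat}, \lambda_{feat},
#' \alpha_{drug}, \lambda_{drug})} in closed form
#' ([eb_update_alpha()], [eb_update_lambda()]).  Prior means of the variance
#' components are modelled as reciprocal linear predictors of external
#' covariates, \eqn{\phi_{jd} = (c_{jd}'\alpha_{feat})^{-1}} and
#' \eqn{\chi_d = (z_d'\alpha_{drug})^{-1}}; intercepts are always included.
#'
#' @param y Response matrix (samples x drugs).  `NA` entries are allowed and
#'   define drug-specific sample subsets.
#' @param X Feature matrix (samples x features).
#' @param feature_covars External feature covariates: either `NULL`
#'   (intercept only), a `p x G` matrix (same covariates for every drug), or
#'   a `(p*D) x G` matrix stacked drug-major (rows ordered drug 1 features
#'   1..p, drug 2 features 1..p, ...).  Do not include an intercept column.
#' @param drug_covars External drug covariates: `NULL` or a `D x H` matrix,
#'   without intercept.
#' @param unpenalized Optional matrix of unpenalized covariates (samples x
#'   u) whose coefficients get a flat prior.
#' @param control A [nig_control()] list.
#' @return An object of class `"nig_fit"` with elements
#'   \describe{
#'     \item{states}{per-drug `"nig_vb"` states (final refit),}
#'     \item{alpha_feat, lambda_feat, alpha_drug, lambda_drug}{estimated (or
#'       pinned) hyperparameters,}
#'     \item{phi, chi}{implied prior means (`p x D` matrix resp. length-`D`
#'       vector),}
#'     \item{beta}{posterior mean coefficients (`p x D`),}
#'     \item{trace}{data frame of hyperparameters per outer iteration,}
#'     \item{centers, scales}{the per-drug response and feature centring
#'       applied, needed for prediction.}
#'   }
#' @examples
#' sim <- sim_scenario(3, n = 60, p = 15, D = 4, seed = 7)
#' fit <- nig_fit(sim$y, sim$X, sim$feature_covars, sim$drug_covars,
#'                control = nig_control(max_iter_em = 10))
#' fit
#' @export
nig_fit <- function(y, X, feature_covars = NULL, drug_covars = NULL,
                    unpenalized = NULL, control = nig_control()) {
  y <- as.matrix(y)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X); D <- ncol(y)
  stopifnot(nrow(y) == n)
  if (!is.null(rownames(y)) && !is.null(rownames(X)) &&
      !identical(rownames(y), rownames(X)))
    stop("sample labels of response and feature matrices do not match")

  prep <- nig_prepare(y, X,
                      center_response = control$center_response,
                      scale_response = control$scale_response,
                      center_features = control$center_features)
  y <- prep$y; X <- prep$X

  C <- .build_feature_design(feature_covars, p, D, control$use_feature_covars)
  Z <- .build_drug_design(drug_covars, D, control$use_drug_covars)

  obs <- !is.na(y)
  if (any(colSums(obs) < 2L)) stop("a drug has fewer than 2 observed samples")
  # with complete responses every drug shares the same Gram matrix
  shared_xtx <- if (all(obs) && is.null(unpenalized) && p <= 1.5 * n)
    crossprod(X) else NULL

  # initial hyperparameters: prior means 1 at both levels
  alpha_feat <- c(1 / control$fixed_phi, rep(0, ncol(C) - 1L))
  alpha_drug <- c(1 / control$fixed_chi, rep(0, ncol(Z) - 1L))
  lambda_feat <- if (control$update_feature) 1 else control$fixed_lambda
  lambda_drug <- if (control$update_drug) 1 else control$fixed_lambda

  states <- vector("list", D)
  hyper_vec <- function() c(alpha_feat, lambda_feat, alpha_drug, lambda_drug)
  trace <- list()

  fit_all <- function() {
    phi_mat <- .implied_means(C, alpha_feat, control$clip_range, "feature")
    dim(phi_mat) <- c(p, D)
    chi_vec <- .implied_means(Z, alpha_drug, control$clip_range, "drug")
    for (d in seq_len(D)) {
      rows <- obs[, d]
      st <- tryCatch(
        nig_vb(X[rows, , drop = FALSE], y[rows, d],
               phi = phi_mat[, d], chi = chi_vec[d],
               lambda_feat = lambda_feat, lambda_drug = lambda_drug,
               unpenalized = if (is.null(unpenalized)) NULL else
                 unpenalized[rows, , drop = FALSE],
               tol = control$tol_vb, max_iter = control$max_iter_vb,
               init = states[[d]], xtx = shared_xtx,
               method = if (is.null(shared_xtx)) "auto" else "dense",
               check = l == 1L),
        error = function(err)
          stop("variational fit failed for drug ", d, ": ",
               conditionMessage(err)))
      states[[d]] <<- st
    }
    list(phi = phi_mat, chi = chi_vec)
  }

  for (l in seq_len(control$max_iter_em)) {
    pm <- fit_all()
    old <- hyper_vec()
    if (control$update_feature) {
      e_all <- unlist(lapply(states, `[[`, "e"), use.names = FALSE)
      b_all <- unlist(lapply(states, `[[`, "b"), use.names = FALSE)
      alpha_feat <- eb_update_alpha(C, e_all)
      lambda_feat <- eb_update_lambda(C, alpha_feat, e_all, b_all, p * D)
    }
    if (control$update_drug) {
      f_all <- vapply(states, `[[`, numeric(1), "f")
      g_all <- vapply(states, `[[`, numeric(1), "g")
      alpha_drug <- eb_update_alpha(Z, f_all)
      lambda_drug <- eb_update_lambda(Z, alpha_drug, f_all, g_all, D)
    }
    new <- hyper_vec()
    trace[[l]] <- new
    rel <- max(abs(new - old) / pmax(abs(old), 1e-12))
    if (control$verbose)
      message(sprintf("outer %3d: max rel hyper change %.3g", l, rel))
    if (rel < control$tol_em) break
  }
  pm <- fit_all()  # final refit under the final hyperparameters

  trace <- as.data.frame(do.call(rbind, trace))
  names(trace) <- c(paste0("alpha_feat", seq_along(alpha_feat) - 1L),
                    "lambda_feat",
                    paste0("alpha_drug", seq_along(alpha_drug) - 1L),
                    "lambda_drug")

  beta <- vapply(states, `[[`, numeric(p), "mu")
  dimnames(beta) <- list(colnames(X), colnames(y))
  out <- list(states = states,
              alpha_feat = alpha_feat, lambda_feat = lambda_feat,
              alpha_drug = alpha_drug, lambda_drug = lambda_drug,
              phi = pm$phi, chi = pm$chi, beta = beta,
              trace = trace, outer_iterations = nrow(trace),
              n = n, p = p, D = D,
              centers = prep$centers, scales = prep$scales,
              feature_centers = prep$feature_centers,
              control = control, call = match.call())
  class(out) <- "nig_fit"
  out
}

#' @export
print.nig_fit <- function(x, ...) {
  cat(sprintf("NIG shrinkage regression fit: n = %d, p = %d, D = %d drugs\n",
              x$n, x$p, x$D))
  cat(sprintf("  outer EM iterations: %d\n", x$outer_iterations))
  cat("  alpha_feat:", format(x$alpha_feat, digits = 4),
      " lambda_feat:", format(x$lambda_feat, digits = 4), "\n")
  cat("  alpha_drug:", format(x$alpha_drug, digits = 4),
      " lambda_drug:", format(x$lambda_drug, digits = 4), "\n")
  cat(sprintf("  implied prior means: phi in [%.3g, %.3g], chi in [%.3g, %.3g]\n",
              min(x$phi), max(x$phi), min(x$chi), max(x$chi)))
  invisible(x)
}

#' @export
coef.nig_fit <- function(object, ...) object$beta

# centre (and optionally scale) responses per drug; centre features
nig_prepare <- function(y, X, center_response = TRUE, scale_response = FALSE,
                        center_features = TRUE) {
  centers <- rep(0, ncol(y))
  scales <- rep(1, ncol(y))
  if (center_response) {
    centers <- colMeans(y, na.rm = TRUE)
    y <- sweep(y, 2L, centers)
  }
  if (scale_response) {
    scales <- apply(y, 2L, stats::sd, na.rm = TRUE)
    if (any(scales == 0)) stop("constant response column cannot be scaled")
    y <- sweep(y, 2L, scales, "/")
  }
  feature_centers <- rep(0, ncol(X))
  if (center_features) {
    feature_centers <- colMeans(X)
    X <- sweep(X, 2L, feature_centers)
  }
  list(y = y, X = X, centers = centers, scales = scales,
       feature_centers = feature_centers)
}

# stacked (p*D) x (G+1) feature-level design, intercept first, drug-major
.build_feature_design <- function(feature_covars, p, D, use_covars) {
  if (is.null(feature_covars) || !use_covars)
    return(matrix(1, p * D, 1L, dimnames = list(NULL, "intercept")))
  fc <- as.matrix(feature_covars)
  if (nrow(fc) == p) fc <- fc[rep(seq_len(p), D), , drop = FALSE]
  if (nrow(fc) != p * D)
    stop("'feature_covars' must have p or p*D rows (drug-major stacking)")
  cn <- colnames(fc)
  if (is.null(cn)) cn <- paste0("c", seq_len(ncol(fc)))
  cbind(intercept = 1, structure(fc, dimnames = list(NULL, cn)))
}

.build_drug_design <- function(drug_covars, D, use_covars) {
  if (is.null(drug_covars) || !use_covars)
    return(matrix(1, D, 1L, dimnames = list(NULL, "intercept")))
  zc <- as.matrix(drug_covars)
  if (nrow(zc) != D) stop("'drug_covars' must have one row per drug")
  cn <- colnames(zc)
  if (is.null(cn)) cn <- paste0("z", seq_len(ncol(zc)))
  cbind(intercept = 1, structure(zc, dimnames = list(NULL, cn)))
}

# implied prior means 1/(c'alpha), clipped into a valid range
.implied_means <- function(covars, alpha, clip_range, level) {
  lp <- drop(covars %*% alpha)
  m <- 1 / lp
  bad <- !is.finite(m) | m < clip_range[1] | m > clip_range[2]
  if (any(bad)) {
    warning(sprintf(
      "%d %s-level linear predictor(s) implied prior means outside [%g, %g]; clipped",
      sum(bad), level, clip_range[1], clip_range[2]), call. = FALSE)
    m[!is.finite(m) | m < 0] <- clip_range[2]  # nonpositive predictor: weak shrinkage
    m <- pmin(pmax(m, clip_range[1]), clip_range[2])
  }
  m
}
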