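#' Predict drug sensitivities from a fitted NIG model
#'
#' Posterior-mean point predictions \eqn{\hat y = X_{new} \hat\beta_d} for
#' every drug.  New features are centred with the training feature means;
#' predictions are returned on the original response scale (training
#' centres and scales are added back).
#'
#' @param object A `"nig_fit"` object.
#' @param newdata Feature matrix (samples x p) on the original scale.
#' @param ... Unused.
#' @return Matrix of predictions (samples x D).
#' @export
predict.nig_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$p)
  Xc <- sweep(newdata, 2L, object$feature_centers)
  pred <- Xc %*% object$beta
  pred <- sweep(pred, 2L, object$scales, "*")
  sweep(pred, 2L, object$centers, "+")
}

#' Prediction mean squared error over drugs and samples
#'
#' \deqn{PMSE = D^{-1} \sum_d n_d^{-1} \sum_i (y_{id} - \hat y_{id})^2,}
#' with missing response entries excluded pairwise (each drug contributes
#' the mean over its observed samples).  On responses standardised to unit
#' variance, predicting zero everywhere (the empty model) gives PMSE close
#' to one, which anchors the scale of reported errors.
#'
#' @param observed,predicted Equal-shaped numeric matrices (samples x
#'   drugs); `observed` may contain `NA`.
#' @return Scalar mean squared error.
#' @export
pmse <- function(observed, predicted) {
  observed <- as.matrix(observed)
  predicted <- as.matrix(predicted)
  stopifnot(identical(dim(observed), dim(predicted)))
  per_drug <- vapply(seq_len(ncol(observed)), function(d) {
    ok <- !is.na(observed[, d]) & !is.na(predicted[, d])
    if (!any(ok)) stop("drug ", d, " has no overlapping observed entries")
    mean((observed[ok, d] - predicted[ok, d])^2)
  }, numeric(1))
  mean(per_drug)
}

#' Cross-validation folds
#'
#' Partition `n` samples into folds of sizes differing by at most one.
#'
#' @param n Number of samples.
#' @param n_folds Number of folds (default 10).
#' @param seed Optional integer seed.
#' @return Integer vector of fold assignments, length `n`.
#' @export
cv_folds <- function(n, n_folds = 10L, seed = NULL) {
  stopifnot(n_folds >= 2L, n >= n_folds)
  if (!is.null(seed)) set.seed(seed)
  sample(rep_len(seq_len(n_folds), n))
}

#' Cross-validated prediction error of the NIG model
#'
#' Estimates the prediction mean squared error by k-fold cross-validation.
#' Following the estimation protocol of the method, hyperparameters are by
#' default estimated once on all samples and then held fixed: within each
#' fold only the per-drug variational posteriors are refit on the training
#' samples before predicting the held-out samples.  A stricter mode refits
#' the hyperparameters inside every fold (`nested = TRUE`).
#'
#' Responses are standardised per drug (centring and unit variance) before
#' fitting so that PMSE is on the scale where the empty model scores one.
#'
#' @inheritParams nig_fit
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param nested Re-estimate hyperparameters inside each training fold?
#' @param fold_assignments Optional explicit integer fold vector.
#' @return List with `pmse_mean` (mean over folds), `pmse_sd` (standard
#'   deviation over folds), `per_fold` (per-fold PMSE), `folds` and the
#'   full-data `fit`.
#' @export
nig_cv <- function(y, X, feature_covars = NULL, drug_covars = NULL,
                   unpenalized = NULL, control = nig_control(),
                   n_folds = 10L, seed = 1L, nested = FALSE,
                   fold_assignments = NULL) {
  y <- as.matrix(y); X <- as.matrix(X)
  n <- nrow(y)
  control$scale_response <- TRUE
  folds <- if (is.null(fold_assignments))
    cv_folds(n, n_folds, seed = seed)
  else as.integer(fold_assignments)
  stopifnot(length(folds) == n)

  full_fit <- nig_fit(y, X, feature_covars, drug_covars, unpenalized, control)

  per_fold <- vapply(sort(unique(folds)), function(k) {
    tr <- folds != k
    te <- !tr
    fit_k <- tryCatch({
      if (nested) {
        nig_fit(y[tr, , drop = FALSE], X[tr, , drop = FALSE],
                feature_covars, drug_covars,
                if (is.null(unpenalized)) NULL else
                  unpenalized[tr, , drop = FALSE], control)
      } else {
        .refit_states(y[tr, , drop = FALSE], X[tr, , drop = FALSE],
                      full_fit, control)
      }
    }, error = function(err)
      stop("cross-validation failed in fold ", k, ": ",
           conditionMessage(err)))
    # scale the held-out responses with the *training* standardisation
    y_te <- sweep(y[te, , drop = FALSE], 2L, fit_k$centers)
    y_te <- sweep(y_te, 2L, fit_k$scales, "/")
    pred <- sweep(X[te, , drop = FALSE], 2L, fit_k$feature_centers) %*%
      fit_k$beta
    pmse(y_te, pred)
  }, numeric(1))

  list(pmse_mean = mean(per_fold), pmse_sd = stats::sd(per_fold),
       per_fold = per_fold, folds = folds, fit = full_fit)
}

# refit per-drug variational states on a sample subset with the
# hyperparameters (hence prior means) taken from an existing fit
.refit_states <- function(y, X, fit, control) {
  prep <- nig_prepare(y, X, center_response = control$center_response,
                      scale_response = control$scale_response,
                      center_features = control$center_features)
  yc <- prep$y
  Xc <- prep$X
  obs <- !is.na(yc)
  beta <- matrix(0, fit$p, fit$D)
  for (d in seq_len(fit$D)) {
    rows <- obs[, d]
    st <- nig_vb(Xc[rows, , drop = FALSE], yc[rows, d],
                 phi = fit$phi[, d], chi = fit$chi[d],
                 lambda_feat = fit$lambda_feat, lambda_drug = fit$lambda_drug,
                 tol = control$tol_vb, max_iter = control$max_iter_vb,
                 init = fit$states[[d]])
    beta[, d] <- st$mu
  }
  list(beta = beta, centers = prep$centers, scales = prep$scales,
       feature_centers = prep$feature_centers, p = fit$p, D = fit$D)
}

#' Decoupled shrinkage and selection (DSS) sparse summary
#'
#' Post-hoc sparsification of a dense posterior-mean fit: the fitted values
#' \eqn{\hat y = X \hat\beta} are approximated by a sparse coefficient
#' vector along an L1 (lasso) path, the path point whose support size is
#' closest to `target_size` is chosen, and the coefficients are refit
#' unpenalised on the selected support.  The heavy-tailed NIG posterior
#' concentrates signal in few coordinates, which is what makes this
#' summary competitive with directly sparse methods.
#'
#' @param X Feature matrix (samples x p) used in the fit.
#' @param beta_mean Posterior mean coefficient vector (length p).
#' @param target_size Desired number of selected features (<= p).
#' @return List of class `"nig_dss"`: `selected` (integer indices),
#'   `coefficients` (length p, zero off the support), `achieved_size`,
#'   `target_size`.  If no path point reaches `target_size` a warning
#'   reports the achieved size.
#' @export
dss_select <- function(X, beta_mean, target_size) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(length(beta_mean) == p, target_size >= 1, target_size <= p)
  yhat <- drop(X %*% beta_mean)
  path <- glmnet::glmnet(X, yhat, family = "gaussian", intercept = TRUE,
                         standardize = FALSE, nlambda = 200L,
                         lambda.min.ratio = 1e-5)
  sizes <- path$df
  best <- which.min(abs(sizes - target_size))
  if (abs(sizes[best] - target_size) > 0 && max(sizes) < target_size)
    warning(sprintf("lasso path reached at most %d features (target %d)",
                    max(sizes), target_size))
  sel <- which(as.numeric(path$beta[, best]) != 0)
  coefs <- numeric(p)
  if (length(sel)) {
    refit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), yhat)
    coefs[sel] <- refit$coefficients[-1L]
    coefs[is.na(coefs)] <- 0
  }
  structure(list(selected = sel, coefficients = coefs,
                 achieved_size = length(sel), target_size = target_size),
            class = "nig_dss")
}

#' @export
print.nig_dss <- function(x, ...) {
  cat(sprintf("DSS sparse summary: %d features selected (target %d)\n",
              x$achieved_size, x$target_size))
  invisible(x)
}

#' Write a PMSE comparison table
#'
#' Writes a methods-by-analyses table of prediction errors as tab-separated
#' text.
#'
#' @param table Numeric matrix with method rows and analysis columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmse_table <- function(table, path) {
  utils::write.table(as.matrix(table), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
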