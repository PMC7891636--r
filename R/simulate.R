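#' Synthetic centred Gaussian design matrix
#'
#' Generates an n x p feature matrix with exchangeable correlation
#' `correlation` between columns (a single shared factor plus independent
#' noise), then centres (and optionally standardises) the columns.  Stands
#' in for real molecular feature matrices so that the simulation study runs
#' without any external download.
#'
#' @param n,p Dimensions.
#' @param correlation Common pairwise correlation in `[0, 1)`; default 0.3,
#'   a moderate level typical of co-expressed gene panels.
#' @param standardize Scale columns to unit variance (default `TRUE`).
#' @param seed Optional integer seed.
#' @return Centred numeric matrix.
#' @export
sim_design <- function(n, p, correlation = 0.3, standardize = TRUE,
                       seed = NULL) {
  stopifnot(n >= 2, p >= 1, correlation >= 0, correlation < 1)
  if (!is.null(seed)) set.seed(seed)
  shared <- stats::rnorm(n)
  X <- sqrt(correlation) * matrix(shared, n, p) +
    sqrt(1 - correlation) * matrix(stats::rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = standardize)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  colnames(X) <- paste0("feature", seq_len(p))
  rownames(X) <- paste0("sample", seq_len(n))
  X
}

#' Dummy-coded group covariates
#'
#' Splits `count` units into `n_groups` approximately equal, contiguous
#' groups and returns the dummy coding with the first group as reference
#' (absorbed by the model intercept).  With reference coding and
#' coefficients \eqn{\alpha = (1, 1, 3, 7)} the implied prior means
#' \eqn{1/(c'\alpha)} are 1, 1/2, 1/4 and 1/8 for the four groups.
#'
#' @param count Number of units (features or drugs).
#' @param n_groups Number of groups (>= 1).
#' @return Matrix `count x (n_groups - 1)` of dummies with a `"groups"`
#'   attribute giving each unit's group index.  For `n_groups = 1` a
#'   zero-column matrix (intercept-only design).
#' @export
group_covariates <- function(count, n_groups) {
  stopifnot(count >= n_groups, n_groups >= 1)
  groups <- sort(rep_len(seq_len(n_groups), count))
  M <- matrix(0, count, n_groups - 1L)
  if (n_groups > 1L) {
    for (k in 2:n_groups) M[groups == k, k - 1L] <- 1
    colnames(M) <- paste0("group", 2:n_groups)
  }
  attr(M, "groups") <- groups
  M
}

#' Permute a fraction of external covariate rows
#'
#' Noise mechanism for degrading external covariates: a uniformly chosen
#' fraction `q` of the rows has its covariate values permuted among
#' themselves, leaving the other rows untouched.  `q = 0` is the identity;
#' `q = 1` permutes all rows (pure noise with the marginal distribution of
#' the covariates preserved).
#'
#' @param covars Covariate matrix (no intercept column).
#' @param q Fraction of rows to permute, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Matrix of the same shape (attributes preserved).
#' @export
permute_covariate_rows <- function(covars, q, seed = NULL) {
  stopifnot(q >= 0, q <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(covars)
  k <- round(q * n)
  if (k < 2L) return(covars)
  rows <- sample.int(n, k)
  out <- covars
  out[rows, ] <- covars[sample(rows), , drop = FALSE]
  out
}

# deterministic per-component substream seed below 2^31
.substream <- function(seed, name) {
  offs <- c(sigma2 = 11L, gamma2 = 23L, tau2 = 37L, beta = 53L,
            noise = 71L, design = 89L, permutation = 101L)
  (as.integer(seed) %% 20000000L) * 100L + offs[[name]]
}

#' Simulate data from the NIG generative model
#'
#' Draws a full synthetic dataset from the hierarchical model under one of
#' four scenarios for the variance components:
#' \describe{
#'   \item{Scenario 1}{global components fixed (\eqn{\tau_d^2 = 1}); local
#'     components \eqn{\gamma_{jd}^2 \sim IG(\phi_{jd}, \lambda_{feat})}
#'     with group-structured prior means,}
#'   \item{Scenario 2}{local components fixed (\eqn{\gamma_{jd}^2 = 1});
#'     global components \eqn{\tau_d^2 \sim IG(\chi_d, \lambda_{drug})}
#'     drawn with group-structured prior means,}
#'   \item{Scenario 3}{both levels drawn from the model,}
#'   \item{Scenario 4}{as Scenario 3, with a fraction `noise_fraction` of
#'     the external covariate rows permuted (see
#'     [permute_covariate_rows()]) to emulate weak co-data.}
#' }
#' The default configuration uses four approximately
#' equal feature groups and four drug groups with true coefficients
#' \eqn{\alpha = (1, 1, 3, 7)} at each structured level (prior means 1,
#' 1/2, 1/4, 1/8), shapes \eqn{\lambda = 1}, error variances
#' \eqn{\sigma_d^2 \sim} inverse-gamma(3, 2) (prior mean and variance both
#' one), n = 507 samples, p = 100 features and D = 251 drugs.  Then
#' \eqn{\beta_{jd} \sim N(0, \gamma_{jd}^2 \tau_d^2 \sigma_d^2)} and
#' \eqn{y_d = X \beta_d + N(0, \sigma_d^2 I)}.
#'
#' All randomness flows from `seed` through named substreams (design,
#' sigma2, gamma2, tau2, beta, noise, permutation), so individual
#' components are reproducible in isolation.
#'
#' @param scenario Integer 1-4.
#' @param n,p,D Numbers of samples, features and drugs.
#' @param n_feature_groups,n_drug_groups Group counts for the dummy-coded
#'   external covariates.
#' @param alpha_feat,alpha_drug True covariate coefficients (length =
#'   group count; first entry is the intercept/reference level).
#' @param lambda_feat,lambda_drug True inverse Gaussian shapes.
#' @param sigma2_shape,sigma2_scale Inverse-gamma parameters of the error
#'   variance distribution.
#' @param noise_fraction Fraction `q` of external covariate rows permuted
#'   (Scenario 4 only).
#' @param design Optional user-supplied n x p design matrix (e.g. real
#'   expression data); defaults to [sim_design()].
#' @param correlation Column correlation for the synthetic design.
#' @param seed Integer seed (required for reproducibility).
#' @return A list of class `"nig_sim"`: `y` (n x D), `X` (n x p),
#'   `feature_covars` (p x (groups-1) dummies), `drug_covars`
#'   (D x (groups-1)), `feature_groups`, `drug_groups`, and `truth` with
#'   all drawn parameters (`beta`, `gamma2`, `tau2`, `sigma2`, `phi`,
#'   `chi`) plus the scenario configuration.
#' @examples
#' sim <- sim_scenario(1, n = 50, p = 20, D = 4, seed = 1)
#' str(sim$truth$tau2)  # all exactly 1 in Scenario 1
#' @export
sim_scenario <- function(scenario, n = 507, p = 100, D = 251,
                         n_feature_groups = 4, n_drug_groups = 4,
                         alpha_feat = c(1, 1, 3, 7),
                         alpha_drug = c(1, 1, 3, 7),
                         lambda_feat = 1, lambda_drug = 1,
                         sigma2_shape = 3, sigma2_scale = 2,
                         noise_fraction = 0, design = NULL,
                         correlation = 0.3, seed = 1) {
  if (!scenario %in% 1:4) stop("'scenario' must be 1, 2, 3 or 4")
  stopifnot(length(alpha_feat) == n_feature_groups,
            length(alpha_drug) == n_drug_groups)

  if (is.null(design)) {
    design <- sim_design(n, p, correlation, seed = .substream(seed, "design"))
  } else {
    design <- as.matrix(design)
    stopifnot(nrow(design) == n, ncol(design) == p)
    design <- scale(design, scale = FALSE)
  }

  fc <- group_covariates(p, n_feature_groups)
  dc <- group_covariates(D, n_drug_groups)
  fgroups <- attr(fc, "groups")
  dgroups <- attr(dc, "groups")
  if (scenario == 4 && noise_fraction > 0) {
    fc_used <- permute_covariate_rows(fc, noise_fraction,
                                      seed = .substream(seed, "permutation"))
    dc_used <- permute_covariate_rows(dc, noise_fraction,
                                      seed = .substream(seed, "permutation") + 1L)
  } else {
    fc_used <- fc
    dc_used <- dc
  }

  # true prior means come from the *unpermuted* group structure
  phi_vec <- drop(1 / (alpha_feat[1] + fc %*% alpha_feat[-1]))
  chi <- drop(1 / (alpha_drug[1] + dc %*% alpha_drug[-1]))
  phi <- matrix(phi_vec, p, D)  # same feature grouping for every drug

  set.seed(.substream(seed, "sigma2"))
  sigma2 <- 1 / stats::rgamma(D, shape = sigma2_shape, rate = sigma2_scale)

  set.seed(.substream(seed, "gamma2"))
  gamma2 <- if (scenario %in% c(1, 3, 4))
    matrix(rinvgauss(p * D, mean = as.vector(phi), shape = lambda_feat), p, D)
  else matrix(1, p, D)

  set.seed(.substream(seed, "tau2"))
  tau2 <- if (scenario %in% c(2, 3, 4))
    rinvgauss(D, mean = chi, shape = lambda_drug)
  else rep(1, D)

  set.seed(.substream(seed, "beta"))
  sd_beta <- sqrt(sweep(gamma2, 2L, tau2 * sigma2, "*"))
  beta <- matrix(stats::rnorm(p * D, sd = as.vector(sd_beta)), p, D)

  set.seed(.substream(seed, "noise"))
  noise <- matrix(stats::rnorm(n * D, sd = rep(sqrt(sigma2), each = n)), n, D)
  y <- design %*% beta + noise
  colnames(y) <- paste0("drug", seq_len(D))
  rownames(y) <- rownames(design)

  structure(list(
    y = y, X = design,
    feature_covars = fc_used, drug_covars = dc_used,
    feature_groups = fgroups, drug_groups = dgroups,
    truth = list(beta = beta, gamma2 = gamma2, tau2 = tau2, sigma2 = sigma2,
                 phi = phi, chi = chi),
    config = list(scenario = scenario, n = n, p = p, D = D,
                  n_feature_groups = n_feature_groups,
                  n_drug_groups = n_drug_groups,
                  alpha_feat = alpha_feat, alpha_drug = alpha_drug,
                  lambda_feat = lambda_feat, lambda_drug = lambda_drug,
                  sigma2_shape = sigma2_shape, sigma2_scale = sigma2_scale,
                  noise_fraction = noise_fraction, seed = seed)),
    class = "nig_sim")
}

#' @export
print.nig_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("NIG simulation, Scenario %d: n = %d, p = %d, D = %d\n",
              cfg$scenario, cfg$n, cfg$p, cfg$D))
  cat(sprintf("  true prior mean range: phi [%.3g, %.3g], chi [%.3g, %.3g]\n",
              min(x$truth$phi), max(x$truth$phi),
              min(x$truth$chi), max(x$truth$chi)))
  invisible(x)
}

#' Write a simulated dataset as delimited text
#'
#' Writes the response, design, external covariates and all truth
#' components of a [sim_scenario()] result as tab-separated files
#' `<prefix>_y.tsv`, `<prefix>_X.tsv`, `<prefix>_feature_covars.tsv`,
#' `<prefix>_drug_covars.tsv`, `<prefix>_truth_*.tsv` plus a JSON-style
#' `<prefix>_config.txt`.
#'
#' @param sim A `"nig_sim"` object.
#' @param prefix Path prefix for the output files.
#' @return Character vector of paths written, invisibly.
#' @export
write_sim <- function(sim, prefix) {
  stopifnot(inherits(sim, "nig_sim"))
  paths <- c(
    y = paste0(prefix, "_y.tsv"), X = paste0(prefix, "_X.tsv"),
    feature_covars = paste0(prefix, "_feature_covars.tsv"),
    drug_covars = paste0(prefix, "_drug_covars.tsv"))
  write_matrix(sim$y, paths["y"])
  write_matrix(sim$X, paths["X"])
  write_matrix(sim$feature_covars, paths["feature_covars"])
  write_matrix(sim$drug_covars, paths["drug_covars"])
  for (nm in names(sim$truth)) {
    pth <- paste0(prefix, "_truth_", nm, ".tsv")
    obj <- sim$truth[[nm]]
    if (is.matrix(obj)) write_matrix(obj, pth)
    else utils::write.table(data.frame(value = obj), pth, sep = "\t",
                            quote = FALSE, row.names = FALSE)
    paths[paste0("truth_", nm)] <- pth
  }
  cfgp <- paste0(prefix, "_config.txt")
  writeLines(.format_config(sim$config), cfgp)
  paths["config"] <- cfgp
  invisible(paths)
}

# minimal JSON-style rendering of a flat config list
.format_config <- function(cfg) {
  render <- function(v) {
    if (length(v) > 1L) paste0("[", paste(v, collapse = ", "), "]")
    else as.character(v)
  }
  c("{", paste0('  "', names(cfg), '": ',
                vapply(cfg, render, character(1)),
                c(rep(",", length(cfg) - 1L), "")), "}")
}
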