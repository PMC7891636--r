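#' Read a labelled numeric matrix from delimited text
#'
#' Reads a comma- or tab-separated file with a header row and a first
#' column of row labels into a numeric matrix.  Non-numeric cells other
#' than the standard missing encodings (`NA`, empty) raise a parse error
#' that names the offending cell.  Missing values are only meaningful in
#' response matrices, where they define drug-specific sample subsets;
#' callers of feature/covariate matrices should pass `allow_na = FALSE`.
#'
#' @param path File path.
#' @param allow_na Permit missing cells?
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path, allow_na = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  M <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(rownames(df), colnames(df)))
  for (j in seq_len(ncol(df))) {
    raw <- trimws(df[[j]])
    empty <- is.na(raw) | raw == "" | raw == "NA"
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & !empty
    if (any(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s' in %s: '%s'",
                   rownames(df)[which(bad)[1]], colnames(df)[j], path,
                   raw[which(bad)[1]]))
    M[, j] <- val
  }
  if (!allow_na && anyNA(M))
    stop("missing values are not allowed in ", path)
  M
}

#' Write a labelled numeric matrix as tab-separated text
#'
#' Inverse of [read_matrix()]: full floating precision, header row, row
#' labels in the first column.
#'
#' @param M Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path) {
  M <- as.matrix(M)
  if (is.null(rownames(M))) rownames(M) <- paste0("row", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("col", seq_len(ncol(M)))
  utils::write.table(format(M, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read and align the inputs of an NIG analysis
#'
#' Loads the response and feature matrices (and optional external
#' covariates) from delimited files, aligns samples by row label, and
#' checks dimensions.  Responses may contain missing cells (drug-specific
#' subsets); all other inputs must be complete.
#'
#' @param response_path Path to the samples x drugs response matrix.
#' @param features_path Path to the samples x features matrix.
#' @param feature_covars_path Optional path to feature covariates
#'   (features x G, or stacked (features*drugs) x G drug-major).
#' @param drug_covars_path Optional path to drug covariates (drugs x H);
#'   row labels must match the response column labels.
#' @return List with `y`, `X`, `feature_covars`, `drug_covars`.
#' @export
read_nig_inputs <- function(response_path, features_path,
                            feature_covars_path = NULL,
                            drug_covars_path = NULL) {
  y <- read_matrix(response_path, allow_na = TRUE)
  X <- read_matrix(features_path, allow_na = FALSE)
  common <- intersect(rownames(y), rownames(X))
  if (length(common) < 2L)
    stop("response and feature matrices share fewer than 2 sample labels")
  if (length(common) < nrow(y) || length(common) < nrow(X))
    message(sprintf("aligning on %d shared samples (response has %d, features %d)",
                    length(common), nrow(y), nrow(X)))
  y <- y[common, , drop = FALSE]
  X <- X[common, , drop = FALSE]
  fc <- if (is.null(feature_covars_path)) NULL else
    read_matrix(feature_covars_path, allow_na = FALSE)
  dc <- if (is.null(drug_covars_path)) NULL else {
    z <- read_matrix(drug_covars_path, allow_na = FALSE)
    if (!setequal(rownames(z), colnames(y)))
      stop("drug covariate row labels do not match response column labels")
    z[colnames(y), , drop = FALSE]
  }
  list(y = y, X = X, feature_covars = fc, drug_covars = dc)
}

#' Write a fitted NIG model as structured text
#'
#' Serialises the hyperparameters, implied prior means, posterior mean
#' coefficients and the outer-iteration trace as a set of tab-separated
#' files with full floating precision: `<prefix>_hyper.tsv`,
#' `<prefix>_beta.tsv`, `<prefix>_phi.tsv`, `<prefix>_chi.tsv`,
#' `<prefix>_trace.tsv`.
#'
#' @param fit A `"nig_fit"` object.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "nig_fit"))
  hyper <- data.frame(
    parameter = c(paste0("alpha_feat", seq_along(fit$alpha_feat) - 1L),
                  "lambda_feat",
                  paste0("alpha_drug", seq_along(fit$alpha_drug) - 1L),
                  "lambda_drug"),
    value = c(fit$alpha_feat, fit$lambda_feat, fit$alpha_drug,
              fit$lambda_drug))
  paths <- c(hyper = paste0(prefix, "_hyper.tsv"),
             beta = paste0(prefix, "_beta.tsv"),
             phi = paste0(prefix, "_phi.tsv"),
             chi = paste0(prefix, "_chi.tsv"),
             trace = paste0(prefix, "_trace.tsv"))
  utils::write.table(format(hyper, digits = 17), paths["hyper"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(fit$beta, paths["beta"])
  write_matrix(fit$phi, paths["phi"])
  utils::write.table(data.frame(drug = seq_along(fit$chi),
                                chi = format(fit$chi, digits = 17)),
                     paths["chi"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(format(fit$trace, digits = 17), paths["trace"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
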