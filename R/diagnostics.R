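#' Applicability-domain and collinearity diagnostics
#'
#' Leverage-based applicability-domain assessment (Williams plot
#' ingredients: hat-matrix diagonals, warning leverage 3p/n,
#' standardized residuals), variance inflation factors, and descriptor
#' mean effects.
#'
#' @name diagnostics
NULL

#' Leverage (hat value) of compounds relative to a fitted model
#'
#' The leverage of compound i is \eqn{h_i = \tilde x_i^T (\tilde X^T
#' \tilde X)^{-1} \tilde x_i}, where \eqn{\tilde x_i} is its
#' intercept-augmented descriptor row and \eqn{\tilde X} the
#' intercept-augmented training design. It measures the compound's
#' distance from the centroid of the training descriptor space; over the
#' training rows the leverages sum to p (descriptors + intercept).
#'
#' @param model a `qsar_model`.
#' @param X descriptor matrix of the compounds to assess (columns matched
#'   to the model by name when named).
#' @return numeric vector of leverages.
#' @export
leverage <- function(model, X) {
  stopifnot(inherits(model, "qsar_model"))
  Xa <- augment_design(model, X)
  rowSums((Xa %*% model$xtx_inv) * Xa)
}

#' Warning leverage threshold
#'
#' \eqn{h^* = 3p/n}, where n is the number of training compounds and p
#' the number of model variables plus one (the intercept). A compound
#' with leverage above h* lies outside the model's applicability domain
#' and is very influential on the fit.
#'
#' @param n number of training compounds.
#' @param p number of fitted parameters (descriptors + 1).
#' @return scalar threshold.
#' @export
#' @examples
#' warning_leverage(29, 6) # 0.6206897
warning_leverage <- function(n, p) {
  if (!is_scalar_number(n) || n <= 0 || !is_scalar_number(p) || p < 1) {
    qsar_abort("need n > 0 and p >= 1", "qsar_config_error")
  }
  3 * p / n
}

#' Williams-plot classification of compounds
#'
#' Computes, for every compound in the dataset, its leverage relative to
#' the trained model and its standardized residual (raw residual divided
#' by the training RMSE), then flags each as `in_domain`,
#' `high_leverage` (h > h* = 3p/n), `outlier` (|standardized residual| >
#' `residual_cutoff`), or `both`. The returned table is exactly the data
#' behind a Williams plot (x = leverage, y = standardized residual, with
#' h* and the residual cutoff as reference lines).
#'
#' @param model a `qsar_model`.
#' @param ds a [qsar_dataset()] containing the model's descriptors.
#' @param residual_cutoff standardized-residual magnitude above which a
#'   compound is flagged as a response outlier (default 3).
#' @return object of class `leverage_report`: list with `table`
#'   (data.frame: compound, split, leverage, std_residual, flag),
#'   `warning_leverage`, `residual_cutoff`.
#' @export
williams_classify <- function(model, ds, residual_cutoff = 3) {
  stopifnot(inherits(model, "qsar_model"), inherits(ds, "qsar_dataset"))
  X <- ds$X[, model$descriptor_names, drop = FALSE]
  pred <- predict(model, X)
  res <- ds$y - pred
  scale_y <- max(abs(ds$y), 1)
  if (model$rmse_train <= 1e-10 * scale_y) {
    # exact interpolation: residuals are roundoff, not signal
    if (any(abs(res) > 1e-7 * scale_y)) {
      qsar_abort("training RMSE is (numerically) zero but residuals are not: cannot standardize",
                 "qsar_degenerate_scale_error")
    }
    std <- res * 0
  } else {
    std <- res / model$rmse_train
  }
  h <- leverage(model, X)
  hstar <- warning_leverage(model$n_train, length(model$descriptor_names) + 1L)
  hi <- h > hstar
  out <- abs(std) > residual_cutoff
  flag <- ifelse(hi & out, "both",
          ifelse(hi, "high_leverage",
          ifelse(out, "outlier", "in_domain")))
  structure(list(table = data.frame(compound = ds$compound_ids,
                                    split = ds$split,
                                    leverage = h,
                                    std_residual = std,
                                    flag = flag,
                                    stringsAsFactors = FALSE,
                                    row.names = NULL),
                 warning_leverage = hstar,
                 residual_cutoff = residual_cutoff),
            class = "leverage_report")
}

#' @export
print.leverage_report <- function(x, ...) {
  tab <- table(factor(x$table$flag,
                      levels = c("in_domain", "high_leverage", "outlier", "both")))
  cat(sprintf("<leverage_report> h* = %.4f, residual cutoff = %g\n",
              x$warning_leverage, x$residual_cutoff))
  cat(sprintf("  %s: %d\n", names(tab), as.integer(tab)), sep = "")
  invisible(x)
}

#' Write Williams-plot data as delimited text
#'
#' One row per compound (compound, split, leverage, std_residual, flag);
#' the warning leverage and residual cutoff are written as `#`-prefixed
#' header metadata so the reference lines of the plot travel with the
#' data.
#'
#' @param x a `leverage_report`.
#' @param path output file.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_williams <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "leverage_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# warning_leverage: %.10g", x$warning_leverage), con)
  writeLines(sprintf("# residual_cutoff: %.10g", x$residual_cutoff), con)
  utils::write.table(x$table, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Variance inflation factors from a correlation matrix
#'
#' \eqn{VIF_j = 1/(1 - R_j^2)}, where \eqn{R_j^2} is the squared multiple
#' correlation of descriptor j regressed on the others; numerically this
#' is the j-th diagonal entry of the inverse correlation matrix. A VIF of
#' 1 means no inter-correlation; 1-5 is acceptable; above 10 the model is
#' considered unstable.
#'
#' @param R symmetric correlation matrix with unit diagonal, positive
#'   definite.
#' @return named numeric vector of VIFs (each >= 1 up to rounding of R).
#' @export
vif_from_correlation <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8 ||
      max(abs(diag(R) - 1)) > 1e-8) {
    qsar_abort("R must be a symmetric correlation matrix with unit diagonal",
               "qsar_config_error")
  }
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    qsar_abort("correlation matrix is not positive definite: descriptors are exactly collinear",
               "qsar_singular_collinearity_error")
  }
  v <- diag(chol2inv(ch))
  names(v) <- rownames(R)
  v
}

#' Variance inflation factors from a descriptor matrix
#'
#' Builds the Pearson correlation matrix of the columns and applies
#' [vif_from_correlation()].
#'
#' @param X descriptor matrix with no constant columns, n > k + 1.
#' @return named numeric vector of VIFs.
#' @export
vif_from_data <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X) + 1L) {
    qsar_abort("VIF needs more compounds than descriptors", "qsar_sample_size_error")
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    qsar_abort(sprintf("constant column '%s': correlation undefined",
                       colnames(X)[which(sds == 0)[1L]]), "qsar_config_error")
  }
  vif_from_correlation(stats::cor(X))
}

# Advisory interpretation of a VIF value.
vif_band <- function(v) {
  ifelse(abs(v - 1) < 1e-8, "no inter-correlation",
  ifelse(v <= 5, "acceptable",
  ifelse(v <= 10, "borderline", "unstable")))
}

#' Collinearity report for a set of descriptors
#'
#' Bundles the pairwise correlation matrix, the VIFs, and the advisory
#' interpretation bands (VIF = 1: none; 1-5 acceptable; > 10 unstable).
#'
#' @param X descriptor matrix.
#' @return object of class `collinearity_report`: list with
#'   `descriptor_names`, `correlation_matrix`, `vif`, `vif_band`.
#' @export
collinearity_report <- function(X) {
  X <- as.matrix(X)
  R <- stats::cor(X)
  v <- vif_from_data(X)
  structure(list(descriptor_names = colnames(X),
                 correlation_matrix = R,
                 vif = v,
                 vif_band = vif_band(v)),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("<collinearity_report>\n")
  print(data.frame(descriptor = x$descriptor_names,
                   VIF = round(x$vif, 4),
                   interpretation = x$vif_band,
                   row.names = NULL))
  invisible(x)
}

#' Descriptor mean effects
#'
#' The mean effect of descriptor j in a fitted linear model is its
#' coefficient-weighted share of the total signal:
#' \deqn{MF_j = \beta_j \sum_i d_{ij} / \sum_k \beta_k \sum_i d_{ik},}
#' where \eqn{d_{ij}} are the training descriptor values. The intercept
#' is excluded from both sums and reported with effect 0. The MF values
#' sum to 1 by construction; the sign of each indicates the direction in
#' which increasing that descriptor moves the predicted activity.
#'
#' @param model a `qsar_model`.
#' @param X_train the training descriptor matrix the model was fitted on.
#' @param tol relative tolerance below which the denominator counts as
#'   zero (default `1e-12`).
#' @return object of class `mean_effect_report`: list with
#'   `descriptor_names`, `mean_effects` (named), `intercept_effect` (0).
#' @export
mean_effects <- function(model, X_train, tol = 1e-12) {
  stopifnot(inherits(model, "qsar_model"))
  X_train <- as.matrix(X_train)
  if (!is.null(colnames(X_train))) {
    X_train <- X_train[, model$descriptor_names, drop = FALSE]
  }
  if (ncol(X_train) != length(model$descriptor_names)) {
    qsar_abort("X_train columns do not match the model", "qsar_schema_error")
  }
  terms <- model$coefficients * colSums(X_train)
  denom <- sum(terms)
  scale <- max(abs(terms), 1)
  if (abs(denom) <= tol * scale) {
    qsar_abort("mean effects undefined: coefficient-weighted descriptor sums cancel",
               "qsar_undefined_mean_effect_error")
  }
  mf <- terms / denom
  structure(list(descriptor_names = model$descriptor_names,
                 mean_effects = stats::setNames(mf, model$descriptor_names),
                 intercept_effect = 0),
            class = "mean_effect_report")
}

#' @export
print.mean_effect_report <- function(x, ...) {
  cat("<mean_effect_report> (intercept effect = 0)\n")
  print(round(x$mean_effects, 6))
  invisible(x)
}
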