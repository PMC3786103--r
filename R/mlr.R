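#' Ordinary least-squares QSAR model
#'
#' Fits pIC50 on a descriptor matrix by OLS with an intercept, retaining
#' everything the downstream diagnostics need: coefficient standard
#' errors, the inverse crossproduct of the intercept-augmented design
#' (for leverages and PRESS), and the training residual scale.
#'
#' @param X numeric matrix (n compounds x k descriptors) with column names.
#' @param y numeric activity vector of length n.
#' @return an object of class `qsar_model` with elements
#'   `descriptor_names`, `intercept`, `coefficients` (named, per
#'   descriptor), `coef_std_errors` (named, intercept first), `n_train`,
#'   `xtx_inv` (the (k+1) x (k+1) inverse crossproduct), `y_train_mean`,
#'   `fitted`, `residuals`, `rmse_train` and `sigma` (residual standard
#'   error with n - k - 1 denominator).
#' @export
#' @examples
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- 1 + X %*% c(2, -1, 0.5) + rnorm(20, sd = 0.1)
#' m <- fit_ols(X, y)
#' m
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  k <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(k))
  if (length(y) != n) qsar_abort("X and y are not conformable", "qsar_schema_error")
  if (n < k + 2L) {
    qsar_abort(sprintf("need at least %d compounds to fit %d descriptors", k + 2L, k),
               "qsar_sample_size_error")
  }
  Xa <- cbind(`(Intercept)` = 1, X)
  p <- k + 1L
  qx <- qr(Xa)
  if (qx$rank < p) {
    aliased <- colnames(Xa)[qx$pivot[(qx$rank + 1L):p]]
    qsar_abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                       paste(aliased, collapse = ", ")),
               "qsar_singular_design_error")
  }
  # Guard against numerically near-singular designs that qr's default
  # tolerance lets through.
  R <- qr.R(qx)
  d <- abs(diag(R))
  if (max(d) / min(d) > 1e12) {
    qsar_abort("design matrix is numerically singular (condition bound exceeded)",
               "qsar_singular_design_error")
  }
  beta <- qr.coef(qx, y)
  fitted <- as.vector(Xa %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(R)
  dimnames(xtx_inv) <- list(colnames(Xa), colnames(Xa))
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  structure(list(descriptor_names = colnames(X),
                 intercept = unname(beta[1L]),
                 coefficients = stats::setNames(beta[-1L], colnames(X)),
                 coef_std_errors = stats::setNames(se, colnames(Xa)),
                 n_train = n,
                 xtx_inv = xtx_inv,
                 y_train_mean = mean(y),
                 fitted = fitted,
                 residuals = res,
                 rmse_train = sqrt(rss / n),
                 sigma = sqrt(sigma2)),
            class = "qsar_model")
}

#' Fit an OLS model on the training rows of a dataset
#'
#' Convenience wrapper around [fit_ols()]: selects the named descriptors
#' and the training rows (all rows when no split is assigned).
#'
#' @param ds a [qsar_dataset()].
#' @param descriptors character vector of descriptor names to include.
#' @return a `qsar_model`.
#' @export
fit_qsar <- function(ds, descriptors = ds$descriptor_names) {
  stopifnot(inherits(ds, "qsar_dataset"))
  missing <- setdiff(descriptors, ds$descriptor_names)
  if (length(missing)) {
    qsar_abort(sprintf("unknown descriptor(s): %s", paste(missing, collapse = ", ")),
               "qsar_schema_error")
  }
  rows <- split_rows(ds, "train")
  fit_ols(ds$X[rows, descriptors, drop = FALSE], ds$y[rows])
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("<qsar_model>\n  ", format_equation(x), "\n", sep = "")
  cat(sprintf("  n_train = %d, RMSE_train = %.4f\n", x$n_train, x$rmse_train))
  invisible(x)
}

#' Format the fitted model as a regression equation
#'
#' Renders `pIC50 = a(SE) + b1(SE) name1 + ...`, the conventional way a
#' QSAR model equation is reported with standard errors in parentheses.
#'
#' @param model a `qsar_model`.
#' @param digits significant digits for coefficients and errors.
#' @return a single string.
#' @export
format_equation <- function(model, digits = 6) {
  stopifnot(inherits(model, "qsar_model"))
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  terms <- sprintf("%s(%s) %s",
                   fmt(model$coefficients),
                   fmt(model$coef_std_errors[-1L]),
                   model$descriptor_names)
  sign_join <- function(parts) {
    out <- parts[1L]
    for (t in parts[-1L]) {
      out <- if (startsWith(t, "-")) paste(out, "-", sub("^-", "", t))
             else paste(out, "+", t)
    }
    out
  }
  head <- sprintf("%s(%s)", fmt(model$intercept), fmt(model$coef_std_errors[1L]))
  paste("pIC50 =", sign_join(c(head, terms)))
}

# Intercept-augmented design for a model, with column checks.
augment_design <- function(model, X) {
  X <- as.matrix(X)
  k <- length(model$descriptor_names)
  if (ncol(X) != k) {
    qsar_abort(sprintf("expected %d descriptor columns, got %d", k, ncol(X)),
               "qsar_schema_error")
  }
  if (!is.null(colnames(X))) {
    if (!setequal(colnames(X), model$descriptor_names)) {
      qsar_abort("descriptor columns do not match the fitted model", "qsar_schema_error")
    }
    X <- X[, model$descriptor_names, drop = FALSE]
  }
  cbind(1, X)
}

#' Predict activity for new compounds
#'
#' @param object a `qsar_model`.
#' @param newdata descriptor matrix (columns matched to the model by name
#'   when named) or a [qsar_dataset()].
#' @param ... unused.
#' @return numeric vector of predicted pIC50 values.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (inherits(newdata, "qsar_dataset")) newdata <- newdata$X
  Xa <- augment_design(object, newdata)
  as.vector(Xa %*% c(object$intercept, object$coefficients))
}

#' Goodness-of-fit statistics for a model on a given set
#'
#' Computes the conventional MLR statistics block: \eqn{R^2 = 1 -
#' RSS/TSS} (TSS about the evaluated set's own mean), adjusted
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-k-1)}, the overall-regression
#' F statistic \eqn{[R^2/k] / [(1-R^2)/(n-k-1)]}, and \eqn{RMSE =
#' \sqrt{RSS/n}}. `r2_adj`, `f_stat` and the leave-one-out `press` are
#' reported for the training role only; a test set gets `r2` and `rmse`.
#' The RMSE uses an n denominator (no degrees-of-freedom correction), the
#' usual convention when a QSAR equation reports "root mean square error".
#'
#' @param model a `qsar_model`.
#' @param X descriptor matrix of the evaluated set.
#' @param y observed activities of the evaluated set.
#' @param role `"train"` or `"test"`.
#' @return an object of class `qsar_stats`: list with `r2`, `r2_adj`,
#'   `f_stat`, `rmse`, `press`, `n`, `k`, `role`.
#' @export
model_statistics <- function(model, X, y, role = c("train", "test")) {
  role <- match.arg(role)
  stopifnot(inherits(model, "qsar_model"))
  y <- as.numeric(y)
  pred <- predict(model, X)
  n <- length(y)
  k <- length(model$descriptor_names)
  rss <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    qsar_abort("constant observed activity: R^2 undefined", "qsar_undefined_stat_error")
  }
  r2 <- 1 - rss / tss
  r2_adj <- f_stat <- press <- NA_real_
  if (role == "train") {
    if (n > k + 1L) {
      r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
      f_stat <- (r2 / k) / ((1 - r2) / (n - k - 1))
    }
    h <- leverage(model, X)
    press <- sum(((y - pred) / (1 - h))^2)
  }
  structure(list(r2 = r2, r2_adj = r2_adj, f_stat = f_stat,
                 rmse = sqrt(rss / n), press = press,
                 n = n, k = k, role = role),
            class = "qsar_stats")
}

#' @export
print.qsar_stats <- function(x, ...) {
  cat(sprintf("<qsar_stats> role = %s, n = %d, k = %d\n", x$role, x$n, x$k))
  cat(sprintf("  R2 = %.4f", x$r2))
  if (x$role == "train") {
    cat(sprintf(", R2_adj = %.4f, F = %.2f, PRESS = %.4f", x$r2_adj, x$f_stat, x$press))
  }
  cat(sprintf(", RMSE = %.4f\n", x$rmse))
  invisible(x)
}

#' Serialize a fitted model to JSON
#' @param model a `qsar_model`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "qsar_model"))
  obj <- list(descriptor_names = model$descriptor_names,
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              coef_std_errors = as.list(model$coef_std_errors),
              n_train = model$n_train,
              y_train_mean = model$y_train_mean,
              rmse_train = model$rmse_train,
              xtx_inv = model$xtx_inv)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
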