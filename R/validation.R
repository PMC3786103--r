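#' Internal and external validation of QSAR regression models
#'
#' All cross-validated coefficients share the form \eqn{Q^2 = 1 -
#' PRESS/TSS}: PRESS pools squared errors of predictions made for
#' compounds excluded from the fit, TSS is taken about the full-sample
#' mean. [q2_loo()] leaves one compound out at a time, [q2_lgo()] leaves
#' random groups out, [q2_boot()] fits on bootstrap resamples and scores
#' the out-of-bag compounds, and [y_randomization()] refits after
#' permuting the response to show the original fit is not chance.
#'
#' @name validation
NULL

# OLS fit on an index subset; returns coefficients of the augmented design
# or NULL when the subset design is rank deficient.
subset_coef <- function(Xa, y, idx) {
  qx <- qr(Xa[idx, , drop = FALSE])
  if (qx$rank < ncol(Xa)) return(NULL)
  qr.coef(qx, y[idx])
}

#' Leave-one-out cross-validated Q2
#'
#' Uses the exact OLS identity \eqn{e_{(-i)} = e_i / (1 - h_i)}: the
#' deleted residual of compound i equals its ordinary residual scaled by
#' one minus its leverage, so no refitting is needed. \eqn{Q^2_{LOO} = 1
#' - \sum e_{(-i)}^2 / TSS}.
#'
#' @param X descriptor matrix (n x k).
#' @param y activity vector.
#' @return scalar Q2 (at most 1; negative when the model predicts worse
#'   than the mean).
#' @export
q2_loo <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  k <- ncol(X)
  if (n < k + 3L) {
    qsar_abort("leave-one-out needs n >= k + 3", "qsar_sample_size_error")
  }
  model <- fit_ols(X, y)
  h <- leverage(model, X)
  if (any(h >= 1 - 1e-10)) {
    qsar_abort("a compound has leverage 1: it is interpolated exactly and cannot be left out",
               "qsar_degenerate_leverage_error")
  }
  press <- sum((model$residuals / (1 - h))^2)
  tss <- sum((y - mean(y))^2)
  1 - press / tss
}

#' Leave-group-out cross-validated Q2
#'
#' Repeatedly partitions the compounds at random into deletion groups of
#' size `ceiling(n * group_fraction)` (the last group may be smaller),
#' predicts each group from a model fitted on its complement, and pools
#' PRESS and TSS over all repeats.
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param group_fraction fraction of compounds per deletion group
#'   (default 0.2, i.e. five deletion groups).
#' @param n_repeats number of random partitions (default 100).
#' @param seed integer seed.
#' @return scalar Q2, deterministic for a given seed.
#' @export
q2_lgo <- function(X, y, group_fraction = 0.2, n_repeats = 100, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  k <- ncol(X)
  gsize <- as.integer(ceiling(n * group_fraction))
  if (gsize < 1L || n - gsize < k + 2L) {
    qsar_abort("deletion group too large to leave a fittable complement",
               "qsar_config_error")
  }
  Xa <- cbind(1, X)
  ybar <- mean(y)
  folds_per_repeat <- ceiling(n / gsize)
  press <- tss <- 0
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      idx <- sample.int(n)
      groups <- split(idx, ceiling(seq_along(idx) / gsize))
      for (g in groups) {
        beta <- subset_coef(Xa, y, setdiff(seq_len(n), g))
        if (is.null(beta)) {
          qsar_abort("rank-deficient complement design in leave-group-out",
                     "qsar_singular_design_error")
        }
        e <- y[g] - as.vector(Xa[g, , drop = FALSE] %*% beta)
        press <- press + sum(e^2)
        tss <- tss + sum((y[g] - ybar)^2)
      }
    }
  })
  1 - press / tss
}

#' Bootstrap out-of-bag Q2
#'
#' For each of `n_boot` resamples (with replacement, size n) the model is
#' refitted on the resample and used to predict the compounds that did
#' not enter it. \eqn{Q^2_{BOOT} = 1 -} (pooled out-of-bag squared error)
#' / (pooled squared deviation of the out-of-bag activities from the
#' full-sample mean). Resamples whose design is rank deficient, or with
#' an empty out-of-bag set, are skipped and counted.
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @return scalar Q2 with attribute `skipped` (number of unusable
#'   resamples); errors if more than half the resamples were skipped.
#' @export
q2_boot <- function(X, y, n_boot = 5000, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  k <- ncol(X)
  if (n < k + 3L) qsar_abort("bootstrap Q2 needs n >= k + 3", "qsar_sample_size_error")
  Xa <- cbind(1, X)
  ybar <- mean(y)
  press <- tss <- 0
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      bag <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), bag)
      beta <- if (length(oob)) subset_coef(Xa, y, bag) else NULL
      if (is.null(beta)) {
        skipped <- skipped + 1L
        next
      }
      e <- y[oob] - as.vector(Xa[oob, , drop = FALSE] %*% beta)
      press <- press + sum(e^2)
      tss <- tss + sum((y[oob] - ybar)^2)
    }
  })
  if (skipped > n_boot / 2) {
    qsar_abort(sprintf("bootstrap unstable: %d of %d resamples had unusable designs",
                       skipped, n_boot), "qsar_instability_error")
  }
  structure(1 - press / tss, skipped = skipped)
}

#' Y-randomization (response permutation) test
#'
#' Each iteration shuffles the activity vector uniformly at random,
#' refits the model on the unchanged descriptors, and records the
#' training R2 and Q2_LOO. A real structure-activity relationship should
#' tower over these chance-level values; comparable values would mean
#' the original fit could be obtained from noise.
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param n_iterations number of permutations (default 10, the size of a
#'   conventionally reported randomization table).
#' @param seed integer seed.
#' @return object of class `y_randomization`: list with `iterations`
#'   (data.frame: no, q2, r2), `n_iterations`, `seed`.
#' @export
y_randomization <- function(X, y, n_iterations = 10, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  k <- ncol(X)
  if (n < k + 3L) qsar_abort("y-randomization needs n >= k + 3", "qsar_sample_size_error")
  perms <- with_seed(seed, replicate(n_iterations, sample(y), simplify = FALSE))
  rows <- lapply(seq_len(n_iterations), function(i) {
    yp <- perms[[i]]
    m <- fit_ols(X, yp)
    tss <- sum((yp - mean(yp))^2)
    data.frame(no = i,
               q2 = q2_loo(X, yp),
               r2 = 1 - sum(m$residuals^2) / tss)
  })
  structure(list(iterations = do.call(rbind, rows),
                 n_iterations = n_iterations, seed = seed),
            class = "y_randomization")
}

#' @export
print.y_randomization <- function(x, ...) {
  cat(sprintf("<y_randomization> %d permutations\n", x$n_iterations))
  cat(sprintf("  max permuted R2 = %.4f, max permuted Q2_LOO = %.4f\n",
              max(x$iterations$r2), max(x$iterations$q2)))
  invisible(x)
}

#' Write a Y-randomization table as delimited text
#'
#' Columns `No`, `Q2`, `R2` — the layout such randomization tables are
#' conventionally reported in.
#'
#' @param x a `y_randomization` result.
#' @param path output file.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_y_randomization <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "y_randomization"))
  df <- x$iterations
  names(df) <- c("No", "Q2", "R2")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' External (test-set) validation
#'
#' Predicts the held-out test compounds and reports \eqn{RMSE_{test} =
#' \sqrt{mean((y - \hat y)^2)}} and \eqn{R^2_{test} = 1 - RSS/TSS} with
#' TSS about the test-set mean. With a single test compound, or a
#' constant test response, R2 is undefined and returned as `NA` with a
#' warning (the RMSE is still meaningful).
#'
#' @param model a `qsar_model`.
#' @param ds a [qsar_dataset()] with a non-empty test split.
#' @return list with `r2_test`, `rmse_test`, `n_test`.
#' @export
external_validation <- function(model, ds) {
  stopifnot(inherits(model, "qsar_model"), inherits(ds, "qsar_dataset"))
  idx <- which(ds$split == "test")
  if (length(idx) == 0L) {
    qsar_abort("dataset has no test compounds", "qsar_config_error")
  }
  yt <- ds$y[idx]
  pred <- predict(model, ds$X[idx, model$descriptor_names, drop = FALSE])
  rmse <- sqrt(mean((yt - pred)^2))
  tss <- sum((yt - mean(yt))^2)
  r2 <- if (length(idx) < 2L || tss == 0) {
    warning("R2_test undefined: test activities are constant or a single compound")
    NA_real_
  } else {
    1 - sum((yt - pred)^2) / tss
  }
  list(r2_test = r2, rmse_test = rmse, n_test = length(idx))
}

#' Run the full internal/external validation battery
#'
#' Convenience wrapper collecting Q2_LOO, Q2_LGO, Q2_BOOT and (when a
#' test split exists) external statistics for one fitted model.
#'
#' @param model a `qsar_model`.
#' @param ds a [qsar_dataset()]; training rows are used for the internal
#'   coefficients.
#' @param lgo_fraction,lgo_repeats leave-group-out settings.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed (split into independent per-routine seeds).
#' @return object of class `validation_stats`: list with `q2_loo`,
#'   `q2_lgo`, `q2_boot`, `r2_test`, `rmse_test`, `n_boot`,
#'   `n_lgo_repeats`.
#' @export
validate_model <- function(model, ds, lgo_fraction = 0.2, lgo_repeats = 100,
                           n_boot = 5000, seed = 1L) {
  stopifnot(inherits(model, "qsar_model"), inherits(ds, "qsar_dataset"))
  rows <- split_rows(ds, "train")
  X <- ds$X[rows, model$descriptor_names, drop = FALSE]
  y <- ds$y[rows]
  seeds <- derive_seeds(seed, 2L)
  r2_test <- rmse_test <- NA_real_
  if (any(ds$split == "test")) {
    ext <- external_validation(model, ds)
    r2_test <- ext$r2_test
    rmse_test <- ext$rmse_test
  }
  structure(list(q2_loo = q2_loo(X, y),
                 q2_lgo = q2_lgo(X, y, lgo_fraction, lgo_repeats, seeds[1L]),
                 q2_boot = as.numeric(q2_boot(X, y, n_boot, seeds[2L])),
                 r2_test = r2_test, rmse_test = rmse_test,
                 n_boot = n_boot, n_lgo_repeats = lgo_repeats),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat("<validation_stats>\n")
  cat(sprintf("  Q2_LOO = %.4f, Q2_LGO = %.4f, Q2_BOOT = %.4f\n",
              x$q2_loo, x$q2_lgo, x$q2_boot))
  if (!is.na(x$rmse_test)) {
    cat(sprintf("  R2_test = %.4f, RMSE_test = %.4f\n", x$r2_test, x$rmse_test))
  }
  invisible(x)
}
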