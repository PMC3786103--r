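#' Descriptor filtering
#'
#' Two reduction steps are applied to a raw descriptor table before
#' variable selection: [remove_constant()] drops descriptors that are
#' constant or almost constant across compounds, and [decorrelate()]
#' enforces a pairwise inter-correlation ceiling, keeping one descriptor
#' from each highly correlated pair. Both return the reduced dataset
#' together with a `filter_report` audit trail.
#'
#' @name preprocessing
NULL

new_filter_report <- function(removed_constant, removed_correlated, kept) {
  structure(list(removed_constant = removed_constant,
                 removed_correlated = removed_correlated,
                 kept = kept),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d descriptors\n", length(x$kept)))
  cat(sprintf("  removed as (near-)constant: %d\n", length(x$removed_constant)))
  cat(sprintf("  removed as inter-correlated: %d\n", nrow(x$removed_correlated)))
  invisible(x)
}

#' Serialize a filter report to JSON
#' @param x a `filter_report`.
#' @param path optional file path; when given the JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
filter_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "filter_report"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Remove constant and near-constant descriptors
#'
#' Descriptors whose sample variance is at or below `variance_tol` carry
#' no information about activity differences and break correlation-based
#' steps downstream, so they are dropped. Survivor order is preserved.
#'
#' @param ds a [qsar_dataset()].
#' @param variance_tol variance at or below which a descriptor counts as
#'   constant (default `1e-8`).
#' @return list with elements `dataset` (reduced) and `report`
#'   (`filter_report`).
#' @export
remove_constant <- function(ds, variance_tol = 1e-8) {
  stopifnot(inherits(ds, "qsar_dataset"))
  if (length(ds$descriptor_names) < 1L) {
    qsar_abort("dataset has no descriptors", "qsar_empty_feature_error")
  }
  if (!is_scalar_number(variance_tol) || variance_tol < 0) {
    qsar_abort("variance_tol must be a non-negative number", "qsar_config_error")
  }
  v <- apply(ds$X, 2L, stats::var)
  drop <- v <= variance_tol
  if (all(drop)) {
    qsar_abort("all descriptors are (near-)constant; nothing left to model",
               "qsar_empty_feature_error")
  }
  report <- new_filter_report(
    removed_constant = ds$descriptor_names[drop],
    removed_correlated = data.frame(dropped = character(), kept = character(),
                                    r = numeric(), stringsAsFactors = FALSE),
    kept = ds$descriptor_names[!drop])
  out <- qsar_dataset(ds$X[, !drop, drop = FALSE], ds$y,
                      compound_ids = ds$compound_ids,
                      descriptor_names = ds$descriptor_names[!drop],
                      split = ds$split)
  list(dataset = out, report = report)
}

#' Drop one descriptor from each highly inter-correlated pair
#'
#' Any surviving pair of descriptors has `|Pearson r| <= threshold`.
#' From each conflicting pair the descriptor with the larger absolute
#' correlation with the activity is kept (ties broken by earlier column
#' order), so the filter is deterministic and activity-relevant. When the
#' dataset carries a train/test split, correlations are computed on the
#' training rows only to avoid test-set leakage; otherwise on all rows.
#'
#' @param ds a [qsar_dataset()] with no constant descriptors.
#' @param threshold maximum tolerated `|r|` between two kept descriptors
#'   (default 0.90).
#' @return list with elements `dataset` and `report`; the report logs
#'   every drop as (dropped, kept, r).
#' @export
decorrelate <- function(ds, threshold = 0.90) {
  stopifnot(inherits(ds, "qsar_dataset"))
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 1) {
    qsar_abort("threshold must lie in (0, 1]", "qsar_config_error")
  }
  rows <- split_rows(ds, "train")
  Xs <- ds$X[rows, , drop = FALSE]
  ys <- ds$y[rows]
  v <- apply(Xs, 2L, stats::var)
  if (any(v == 0)) {
    qsar_abort(sprintf("constant descriptor '%s' present; run remove_constant first",
                       ds$descriptor_names[which(v == 0)[1L]]),
               "qsar_config_error")
  }
  k <- ncol(Xs)
  C <- abs(stats::cor(Xs))
  ry <- abs(as.vector(stats::cor(Xs, ys)))
  # Visit descriptors from most to least activity-correlated (ties: original
  # column order); greedily keep each one unless it conflicts with an
  # already-kept descriptor.
  order_idx <- order(-ry, seq_len(k))
  kept_idx <- integer(0)
  drops <- list()
  for (j in order_idx) {
    conflict <- kept_idx[C[j, kept_idx] > threshold]
    if (length(conflict) == 0L) {
      kept_idx <- c(kept_idx, j)
    } else {
      partner <- conflict[which.max(C[j, conflict])]
      drops[[length(drops) + 1L]] <- data.frame(
        dropped = ds$descriptor_names[j],
        kept = ds$descriptor_names[partner],
        r = stats::cor(Xs[, j], Xs[, partner]),
        stringsAsFactors = FALSE)
    }
  }
  kept_idx <- sort(kept_idx)
  removed_correlated <- if (length(drops)) do.call(rbind, drops)
                        else data.frame(dropped = character(), kept = character(),
                                        r = numeric(), stringsAsFactors = FALSE)
  report <- new_filter_report(removed_constant = character(),
                              removed_correlated = removed_correlated,
                              kept = ds$descriptor_names[kept_idx])
  out <- qsar_dataset(ds$X[, kept_idx, drop = FALSE], ds$y,
                      compound_ids = ds$compound_ids,
                      descriptor_names = ds$descriptor_names[kept_idx],
                      split = ds$split)
  list(dataset = out, report = report)
}
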