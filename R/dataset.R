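#' QSAR dataset container
#'
#' Bundles a compound-by-descriptor matrix with the modelled activity
#' (pIC50) and an optional train/test assignment. All downstream stages
#' (filtering, selection, regression, validation, applicability domain)
#' operate on this container.
#'
#' @param X numeric matrix, rows = compounds, columns = descriptors.
#' @param y numeric vector of pIC50 values (\eqn{-\log_{10}} of molar IC50),
#'   one per compound.
#' @param compound_ids character vector of unique compound labels; defaults
#'   to `rownames(X)`.
#' @param descriptor_names character vector of unique descriptor labels;
#'   defaults to `colnames(X)`.
#' @param split per-compound assignment, each `"train"`, `"test"` or
#'   `"unassigned"`; defaults to all `"unassigned"`.
#'
#' @return An object of class `qsar_dataset`: a list with elements
#'   `compound_ids`, `descriptor_names`, `X`, `y`, `split`.
#' @export
#' @examples
#' X <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("c", 1:4), paste0("d", 1:3)))
#' ds <- qsar_dataset(X, y = rnorm(4))
#' ds
qsar_dataset <- function(X, y, compound_ids = rownames(X),
                         descriptor_names = colnames(X), split = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (is.null(compound_ids)) compound_ids <- paste0("compound_", seq_len(nrow(X)))
  if (is.null(descriptor_names)) descriptor_names <- paste0("D", seq_len(ncol(X)))
  compound_ids <- as.character(compound_ids)
  descriptor_names <- as.character(descriptor_names)
  if (nrow(X) != length(y) || nrow(X) != length(compound_ids)) {
    qsar_abort("rows of X, length of y and compound_ids must agree",
               "qsar_integrity_error")
  }
  if (ncol(X) != length(descriptor_names)) {
    qsar_abort("columns of X must match descriptor_names", "qsar_integrity_error")
  }
  if (anyDuplicated(compound_ids)) {
    dup <- compound_ids[duplicated(compound_ids)][1L]
    qsar_abort(sprintf("duplicated compound id: '%s'", dup), "qsar_integrity_error")
  }
  if (anyDuplicated(descriptor_names)) {
    dup <- descriptor_names[duplicated(descriptor_names)][1L]
    qsar_abort(sprintf("duplicated descriptor name: '%s'", dup), "qsar_integrity_error")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    qsar_abort(sprintf("missing/non-finite descriptor value at compound '%s', descriptor '%s'",
                       compound_ids[bad[1L]], descriptor_names[bad[2L]]),
               "qsar_parse_error")
  }
  if (anyNA(y) || any(!is.finite(y))) {
    bad <- which(!is.finite(y))[1L]
    qsar_abort(sprintf("missing/non-finite activity for compound '%s'", compound_ids[bad]),
               "qsar_parse_error")
  }
  if (is.null(split)) split <- rep("unassigned", nrow(X))
  split <- as.character(split)
  if (length(split) != nrow(X) || !all(split %in% c("train", "test", "unassigned"))) {
    qsar_abort("split must assign each compound to train/test/unassigned",
               "qsar_integrity_error")
  }
  dimnames(X) <- list(compound_ids, descriptor_names)
  structure(list(compound_ids = compound_ids,
                 descriptor_names = descriptor_names,
                 X = X, y = y, split = split),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("<qsar_dataset> %d compounds x %d descriptors\n",
              length(x$compound_ids), length(x$descriptor_names)))
  cat(sprintf("  split: %d train / %d test / %d unassigned\n",
              sum(x$split == "train"), sum(x$split == "test"),
              sum(x$split == "unassigned")))
  cat(sprintf("  pIC50 range: [%.3f, %.3f]\n", min(x$y), max(x$y)))
  invisible(x)
}

#' @export
dim.qsar_dataset <- function(x) dim(x$X)

#' @export
as.data.frame.qsar_dataset <- function(x, ...) {
  data.frame(compound = x$compound_ids, pIC50 = x$y,
             as.data.frame(x$X, check.names = FALSE),
             split = x$split, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Row indices of a given split role; all rows when nothing is assigned.
split_rows <- function(ds, role = "train") {
  idx <- which(ds$split == role)
  if (length(idx) == 0L && !any(ds$split %in% c("train", "test"))) {
    idx <- seq_along(ds$y)
  }
  idx
}

#' Convert micromolar IC50 to pIC50
#'
#' pIC50 is \eqn{-\log_{10}} of the IC50 expressed in mol/L; for an IC50
#' given in micromolar this is \eqn{6 - \log_{10}(\mathrm{IC50}_{\mu M})}.
#'
#' @param ic50_um positive IC50 value(s) in micromolar.
#' @param compound optional compound label(s) used in error messages.
#' @return numeric vector of pIC50 values.
#' @export
#' @examples
#' ic50_to_pic50(1)    # 6
#' ic50_to_pic50(0.01) # 8
ic50_to_pic50 <- function(ic50_um, compound = NULL) {
  ic50_um <- as.numeric(ic50_um)
  bad <- !is.finite(ic50_um) | ic50_um <= 0
  if (any(bad)) {
    who <- if (!is.null(compound)) as.character(compound)[which(bad)[1L]]
           else as.character(which(bad)[1L])
    qsar_abort(sprintf("IC50 must be positive and finite (compound '%s')", who),
               "qsar_value_error")
  }
  6 - log10(ic50_um)
}

# Guess the field separator of a delimited header line: tab wins if present.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a QSAR descriptor table from delimited text
#'
#' Expects one header row; one id column, one activity column, and any
#' number of numeric descriptor columns. An optional `split` column
#' (values `train`/`test`/`unassigned`) is honoured if present.
#'
#' @param path file path (comma- or tab-delimited; auto-detected unless
#'   `sep` is given).
#' @param activity_column name of the activity column.
#' @param id_column name of the compound-id column.
#' @param activity_unit `"pIC50"` (used verbatim) or `"uM_IC50"`
#'   (converted via [ic50_to_pic50()]). An explicit unit is required
#'   because silently mistaking micromolar IC50 for pIC50 is the classic
#'   QSAR failure mode.
#' @param sep field separator; `NULL` to auto-detect.
#' @param split_column name of an optional split column.
#' @return a [qsar_dataset()].
#' @export
read_qsar <- function(path, activity_column, id_column = "compound",
                      activity_unit = c("pIC50", "uM_IC50"),
                      sep = NULL, split_column = "split") {
  activity_unit <- match.arg(activity_unit)
  if (!file.exists(path)) qsar_abort(sprintf("file not found: %s", path), "qsar_io_error")
  if (is.null(sep)) sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           fileEncoding = "UTF-8")
  for (col in c(id_column, activity_column)) {
    if (!col %in% names(raw)) {
      qsar_abort(sprintf("required column '%s' not found in %s", col, path),
                 "qsar_schema_error")
    }
  }
  ids <- raw[[id_column]]
  split <- NULL
  desc_cols <- setdiff(names(raw), c(id_column, activity_column))
  if (split_column %in% desc_cols) {
    split <- raw[[split_column]]
    desc_cols <- setdiff(desc_cols, split_column)
  }
  if (length(desc_cols) == 0L) {
    qsar_abort("no descriptor columns found", "qsar_schema_error")
  }
  parse_num <- function(vals, colname) {
    out <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(out) & !is.na(vals))
    if (length(bad)) {
      qsar_abort(sprintf("non-numeric value '%s' at row %d, column '%s'",
                         vals[bad[1L]], bad[1L], colname), "qsar_parse_error")
    }
    out
  }
  X <- vapply(desc_cols, function(cn) parse_num(raw[[cn]], cn), numeric(nrow(raw)))
  X <- matrix(X, nrow = nrow(raw), dimnames = list(NULL, desc_cols))
  activity <- parse_num(raw[[activity_column]], activity_column)
  y <- if (activity_unit == "uM_IC50") ic50_to_pic50(activity, compound = ids) else activity
  qsar_dataset(X, y, compound_ids = ids, descriptor_names = desc_cols, split = split)
}

#' Write a QSAR dataset to delimited text
#'
#' Emits id, pIC50, descriptors and the split column. Numeric values are
#' written with 17 significant digits so a write/read round trip is
#' bit-exact for doubles.
#'
#' @param ds a [qsar_dataset()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_qsar <- function(ds, path, sep = ",") {
  df <- as.data.frame(ds)
  num_cols <- vapply(df, is.numeric, logical(1L))
  df[num_cols] <- lapply(df[num_cols], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Randomly split compounds into training and test sets
#'
#' Assigns `round(n * test_fraction)` compounds to the test set and the
#' remainder to training; with 36 compounds and `test_fraction = 0.2`
#' this reproduces the conventional 29 train / 7 test partition. The
#' assignment is a deterministic function of `seed`.
#'
#' @param ds a [qsar_dataset()].
#' @param test_fraction fraction of compounds held out, in (0, 1).
#' @param seed integer seed controlling the random assignment.
#' @return the dataset with its `split` field populated.
#' @export
split_train_test <- function(ds, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(ds, "qsar_dataset"))
  if (!is_scalar_number(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    qsar_abort("test_fraction must lie strictly between 0 and 1", "qsar_config_error")
  }
  n <- length(ds$y)
  if (n < 5L) qsar_abort("need at least 5 compounds to split", "qsar_config_error")
  n_test <- as.integer(round(n * test_fraction))
  test_idx <- with_seed(seed, sample.int(n, n_test))
  split <- rep("train", n)
  split[test_idx] <- "test"
  ds$split <- split
  ds
}
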