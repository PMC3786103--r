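#' Pipeline configuration
#'
#' Collects every setting of the end-to-end workflow — input, activity
#' unit, split, filtering, selection, validation, applicability domain,
#' output — with the defaults used throughout the package. All
#' randomness is funnelled through the explicit per-stage seeds recorded
#' here, so a run is fully described by its resolved configuration.
#'
#' @param input path to a delimited descriptor table, or a
#'   [qsar_dataset()] directly.
#' @param activity_column,id_column,activity_unit,sep column mapping and
#'   unit for [read_qsar()] (ignored when `input` is already a dataset).
#' @param test_fraction held-out fraction for [split_train_test()]; `NULL`
#'   to keep an existing split (or use all rows for training).
#' @param split_seed seed of the random split.
#' @param variance_tol near-constant filter tolerance.
#' @param cor_threshold inter-correlation ceiling for [decorrelate()].
#' @param selection `"ga"`, `"stepwise"` or `"none"`.
#' @param descriptors fixed descriptor list used when `selection =
#'   "none"`.
#' @param ga a [ga_config()].
#' @param enter_p,remove_p stepwise thresholds.
#' @param max_variables stepwise subset bound.
#' @param lgo_fraction,lgo_repeats,n_boot,n_yrand validation settings.
#' @param validation_seed,yrand_seed seeds of the validation battery.
#' @param residual_cutoff Williams-plot standardized-residual cutoff.
#' @param output_dir directory the report bundle is written to; `NULL`
#'   for an in-memory run only.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input,
                            activity_column = "pIC50",
                            id_column = "compound",
                            activity_unit = "pIC50",
                            sep = NULL,
                            test_fraction = 0.2,
                            split_seed = 1L,
                            variance_tol = 1e-8,
                            cor_threshold = 0.90,
                            selection = c("ga", "stepwise", "none"),
                            descriptors = NULL,
                            ga = ga_config(),
                            enter_p = 0.05,
                            remove_p = 0.10,
                            max_variables = 30L,
                            lgo_fraction = 0.2,
                            lgo_repeats = 100L,
                            n_boot = 5000L,
                            n_yrand = 10L,
                            validation_seed = 1L,
                            yrand_seed = 1L,
                            residual_cutoff = 3,
                            output_dir = NULL) {
  selection <- match.arg(selection)
  if (selection == "none" && is.null(descriptors)) {
    qsar_abort("selection = 'none' requires an explicit descriptor list",
               "qsar_config_error")
  }
  structure(list(input = input, activity_column = activity_column,
                 id_column = id_column, activity_unit = activity_unit,
                 sep = sep, test_fraction = test_fraction,
                 split_seed = as.integer(split_seed),
                 variance_tol = variance_tol, cor_threshold = cor_threshold,
                 selection = selection, descriptors = descriptors,
                 ga = ga, enter_p = enter_p, remove_p = remove_p,
                 max_variables = as.integer(max_variables),
                 lgo_fraction = lgo_fraction,
                 lgo_repeats = as.integer(lgo_repeats),
                 n_boot = as.integer(n_boot),
                 n_yrand = as.integer(n_yrand),
                 validation_seed = as.integer(validation_seed),
                 yrand_seed = as.integer(yrand_seed),
                 residual_cutoff = residual_cutoff,
                 output_dir = output_dir),
            class = "pipeline_config")
}

stage_log <- function(fmt, ...) message(sprintf(paste0("[qsarga] ", fmt), ...))

#' Run the full GA-MLR QSAR pipeline
#'
#' Executes load, split, constant-descriptor removal, inter-correlation
#' filtering, variable selection, OLS fitting, the train/test statistics
#' block, the Q2 validation battery, Y-randomization, and the
#' applicability-domain and collinearity diagnostics. Each stage is
#' logged to stderr with its counts and seeds. When
#' `config$output_dir` is set the bundle is also written to disk:
#' a machine-readable `summary.json` embedding the resolved
#' configuration, plus human-readable tables (model equation,
#' Y-randomization, correlation matrix, descriptor MF/VIF table,
#' Williams-plot data, filter audit log). Two runs with the same
#' configuration produce byte-identical summaries.
#'
#' @param config a [pipeline_config()].
#' @return object of class `qsar_report`: list with `dataset`,
#'   `filter_constant`, `filter_correlated`, `selection` (GA result,
#'   stepwise names, or the fixed list), `model`, `train_stats`,
#'   `test_stats`, `validation`, `y_randomization`, `williams`,
#'   `collinearity`, `mean_effects`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- if (inherits(config$input, "qsar_dataset")) config$input
        else read_qsar(config$input, activity_column = config$activity_column,
                       id_column = config$id_column,
                       activity_unit = config$activity_unit, sep = config$sep)
  stage_log("loaded %d compounds x %d descriptors", nrow(ds$X), ncol(ds$X))
  if (!is.null(config$test_fraction) && !any(ds$split %in% c("train", "test"))) {
    ds <- split_train_test(ds, config$test_fraction, config$split_seed)
    stage_log("split: %d train / %d test (seed %d)",
              sum(ds$split == "train"), sum(ds$split == "test"), config$split_seed)
  }
  fc <- remove_constant(ds, config$variance_tol)
  stage_log("constant filter: removed %d, kept %d",
            length(fc$report$removed_constant), length(fc$report$kept))
  fd <- decorrelate(fc$dataset, config$cor_threshold)
  stage_log("correlation filter (|r| > %g): removed %d, kept %d",
            config$cor_threshold, nrow(fd$report$removed_correlated),
            length(fd$report$kept))
  ds2 <- fd$dataset

  sel_result <- NULL
  selected <- switch(config$selection,
    ga = {
      sel_result <- ga_select(ds2, config$ga)
      stage_log("GA: best Q2_cv = %.4f over %d generations (seed %d)",
                sel_result$best_fitness, sel_result$generations_run,
                config$ga$seed)
      sel_result$best_descriptors
    },
    stepwise = {
      s <- stepwise_select(ds2, config$enter_p, config$remove_p,
                           config$max_variables)
      stage_log("stepwise: selected %d descriptors", length(s))
      s
    },
    none = intersect(config$descriptors, ds2$descriptor_names))
  if (length(selected) == 0L) {
    qsar_abort("variable selection returned no descriptors", "qsar_empty_feature_error")
  }

  model <- fit_qsar(ds2, selected)
  rows_tr <- split_rows(ds2, "train")
  Xtr <- ds2$X[rows_tr, selected, drop = FALSE]
  ytr <- ds2$y[rows_tr]
  train_stats <- model_statistics(model, Xtr, ytr, "train")
  stage_log("model: %s", format_equation(model, digits = 4))
  test_stats <- NULL
  if (any(ds2$split == "test")) {
    idx <- which(ds2$split == "test")
    test_stats <- model_statistics(model, ds2$X[idx, selected, drop = FALSE],
                                   ds2$y[idx], "test")
  }
  validation <- validate_model(model, ds2,
                               lgo_fraction = config$lgo_fraction,
                               lgo_repeats = config$lgo_repeats,
                               n_boot = config$n_boot,
                               seed = config$validation_seed)
  stage_log("validation: Q2_LOO = %.4f, Q2_LGO = %.4f, Q2_BOOT = %.4f",
            validation$q2_loo, validation$q2_lgo, validation$q2_boot)
  yr <- y_randomization(Xtr, ytr, config$n_yrand, config$yrand_seed)
  williams <- williams_classify(model, ds2, config$residual_cutoff)
  coll <- collinearity_report(Xtr)
  mf <- mean_effects(model, Xtr)

  report <- structure(list(dataset = ds2,
                           filter_constant = fc$report,
                           filter_correlated = fd$report,
                           selection = if (!is.null(sel_result)) sel_result else selected,
                           selected_descriptors = selected,
                           model = model,
                           train_stats = train_stats,
                           test_stats = test_stats,
                           validation = validation,
                           y_randomization = yr,
                           williams = williams,
                           collinearity = coll,
                           mean_effects = mf,
                           config = config),
                      class = "qsar_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.qsar_report <- function(x, ...) {
  cat("<qsar_report>\n")
  cat("  ", format_equation(x$model, digits = 4), "\n", sep = "")
  cat(sprintf("  R2_train = %.4f, Q2_LOO = %.4f", x$train_stats$r2,
              x$validation$q2_loo))
  if (!is.null(x$test_stats)) cat(sprintf(", R2_test = %.4f", x$test_stats$r2))
  cat("\n")
  invisible(x)
}

# Resolved configuration as plain lists for JSON embedding.
config_as_list <- function(config) {
  out <- unclass(config)
  out$ga <- unclass(out$ga)
  if (inherits(out$input, "qsar_dataset")) {
    out$input <- sprintf("<in-memory qsar_dataset: %d x %d>",
                         nrow(out$input$X), ncol(out$input$X))
  }
  out
}

#' Write a pipeline report bundle to a directory
#'
#' Files written: `summary.json` (statistics, selected descriptors,
#' diagnostics and the full resolved configuration), `model_equation.txt`,
#' `y_randomization.tsv`, `correlation_matrix.tsv`, `descriptor_table.tsv`
#' (coefficient, SE, mean effect, VIF per descriptor), `williams.tsv`,
#' `filter_report.json` and `fitness_trace.tsv` (GA runs).
#'
#' @param report a `qsar_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "qsar_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- report$model
  summary <- list(
    config = config_as_list(report$config),
    n_compounds = length(report$dataset$y),
    n_train = m$n_train,
    n_test = sum(report$dataset$split == "test"),
    selected_descriptors = report$selected_descriptors,
    equation = format_equation(m),
    coefficients = as.list(c("(Intercept)" = m$intercept, m$coefficients)),
    std_errors = as.list(m$coef_std_errors),
    train_stats = unclass(report$train_stats),
    test_stats = if (!is.null(report$test_stats)) unclass(report$test_stats),
    validation = unclass(report$validation),
    y_randomization = report$y_randomization$iterations,
    warning_leverage = report$williams$warning_leverage,
    domain_flags = as.list(table(report$williams$table$flag)),
    vif = as.list(report$collinearity$vif),
    mean_effects = as.list(report$mean_effects$mean_effects))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(format_equation(m), file.path(dir, "model_equation.txt"))
  write_y_randomization(report$y_randomization,
                        file.path(dir, "y_randomization.tsv"))
  utils::write.table(data.frame(descriptor = rownames(report$collinearity$correlation_matrix),
                                report$collinearity$correlation_matrix,
                                check.names = FALSE),
                     file.path(dir, "correlation_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(
    descriptor = c("(Intercept)", m$descriptor_names),
    coefficient = c(m$intercept, m$coefficients),
    std_error = m$coef_std_errors,
    mean_effect = c(report$mean_effects$intercept_effect,
                    report$mean_effects$mean_effects),
    vif = c(NA, report$collinearity$vif),
    vif_interpretation = c(NA, report$collinearity$vif_band),
    check.names = FALSE),
    file.path(dir, "descriptor_table.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_williams(report$williams, file.path(dir, "williams.tsv"))
  filter_report_json(report$filter_constant,
                     file.path(dir, "filter_constant.json"))
  filter_report_json(report$filter_correlated,
                     file.path(dir, "filter_correlated.json"))
  if (inherits(report$selection, "ga_result")) {
    utils::write.table(data.frame(generation = seq_along(report$selection$fitness_trace) - 1L,
                                  best_fitness = report$selection$fitness_trace),
                       file.path(dir, "fitness_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ga_result_json(report$selection, file.path(dir, "ga_result.json"))
  }
  invisible(dir)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys are the arguments of [pipeline_config()]; a `ga` block
#' holds [ga_config()] keys.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  if (!is.null(vals$ga)) vals$ga <- do.call(ga_config, vals$ga)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    qsar_abort(sprintf("unknown pipeline config key(s): %s",
                       paste(unknown, collapse = ", ")), "qsar_config_error")
  }
  do.call(pipeline_config, vals)
}
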