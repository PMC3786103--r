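#' Variable selection for QSAR regression
#'
#' Two selection strategies over a candidate descriptor pool: a genetic
#' algorithm whose fitness is the cross-validated explained variance of
#' the OLS model encoded by each chromosome ([ga_select()]), and a
#' classical forward/backward stepwise search on partial-F p-values
#' ([stepwise_select()]).
#'
#' @name variable_selection
NULL

#' Genetic-algorithm configuration
#'
#' Defaults follow the conventional small-population GA used for
#' descriptor selection in QSAR work: 30 chromosomes, about five active
#' descriptors per initial chromosome, at most 30 descriptors per model,
#' 1\% per-gene mutation, 50\% crossover probability, and a fitness based
#' on cross-validated explained variance with five deletion groups.
#'
#' @param population_size chromosomes per generation.
#' @param mean_initial_variables expected number of active genes in each
#'   initial chromosome.
#' @param max_variables maximum descriptors allowed in one chromosome.
#' @param mutation_prob per-gene mutation probability, in (0, 1).
#' @param crossover_prob probability a selected pair recombines, in (0, 1].
#' @param cv_groups number of cross-validation deletion groups (>= 2).
#' @param fitness_repeats number of independent deletion-group shuffles
#'   the fitness is averaged over (default 10). A Q2 from one random
#'   split of ~30 compounds is noisy enough for the search to chase
#'   split-specific accidents; averaging over a few deterministic
#'   reshuffles stabilizes the ranking of subsets.
#' @param parsimony_penalty selection-score cost per active gene. A
#'   subset search can always buy a little apparent cross-validated Q2
#'   by adding variables that fit quirks of the finite sample, so during
#'   selection chromosomes compete on `Q2_cv - parsimony_penalty *
#'   n_variables`; a larger model must earn its keep. The reported
#'   fitness values are always the plain Q2_cv. Set to 0 to disable.
#' @param max_generations generation budget.
#' @param stagnation_generations stop after this many generations without
#'   improvement of the best fitness.
#' @param seed integer seed governing the whole run.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 30L,
                      mean_initial_variables = 5L,
                      max_variables = 30L,
                      mutation_prob = 0.01,
                      crossover_prob = 0.50,
                      cv_groups = 5L,
                      fitness_repeats = 10L,
                      parsimony_penalty = 0.025,
                      max_generations = 200L,
                      stagnation_generations = 30L,
                      seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              mean_initial_variables = as.integer(mean_initial_variables),
              max_variables = as.integer(max_variables),
              mutation_prob = mutation_prob,
              crossover_prob = crossover_prob,
              cv_groups = as.integer(cv_groups),
              fitness_repeats = as.integer(fitness_repeats),
              parsimony_penalty = parsimony_penalty,
              max_generations = as.integer(max_generations),
              stagnation_generations = as.integer(stagnation_generations),
              seed = as.integer(seed))
  if (cfg$population_size < 2L ||
      !is_scalar_number(cfg$mutation_prob) || cfg$mutation_prob <= 0 ||
      cfg$mutation_prob >= 1 ||
      !is_scalar_number(cfg$crossover_prob) || cfg$crossover_prob <= 0 ||
      cfg$crossover_prob > 1 ||
      cfg$cv_groups < 2L || cfg$max_variables < 1L || cfg$fitness_repeats < 1L ||
      !is_scalar_number(cfg$parsimony_penalty) || cfg$parsimony_penalty < 0 ||
      cfg$max_generations < 0L || cfg$stagnation_generations < 1L) {
    qsar_abort("invalid genetic-algorithm configuration", "qsar_config_error")
  }
  structure(cfg, class = "ga_config")
}

#' Read a GA configuration from a YAML or JSON file
#'
#' Keys are the argument names of [ga_config()]; absent keys keep their
#' defaults.
#'
#' @param path file path (.yaml/.yml/.json).
#' @return a `ga_config`.
#' @export
read_ga_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  known <- names(formals(ga_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    qsar_abort(sprintf("unknown GA config key(s): %s", paste(unknown, collapse = ", ")),
               "qsar_config_error")
  }
  do.call(ga_config, vals)
}

# Contiguous-after-shuffle deletion groups: a list of index vectors whose
# sizes differ by at most one, deterministic under the seed.
make_folds <- function(n, cv_groups, seed) {
  idx <- with_seed(seed, sample.int(n))
  sizes <- diff(round(seq(0, n, length.out = cv_groups + 1L)))
  split(idx, rep(seq_len(cv_groups), times = sizes))
}

# Cross-validated Q2 of the OLS model on the given columns, over
# precomputed folds. -Inf when any complement design is rank deficient.
cv_q2_folds <- function(X, y, cols, folds) {
  n <- length(y)
  Xa <- cbind(1, X[, cols, drop = FALSE])
  press <- 0
  for (g in folds) {
    beta <- subset_coef(Xa, y, setdiff(seq_len(n), g))
    if (is.null(beta)) return(-Inf)
    e <- y[g] - as.vector(Xa[g, , drop = FALSE] %*% beta)
    press <- press + sum(e^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Cross-validated fitness of a chromosome
#'
#' The fitness of a descriptor subset is \eqn{Q^2 = 1 - PRESS/TSS}
#' computed over `cv_groups` random deletion groups (a shuffled split
#' deterministic in `seed`), refitting the OLS model on each group's
#' complement. Maximizing this fitness is the same as minimizing PRESS.
#'
#' @param ds a [qsar_dataset()]; training rows are used.
#' @param genes logical/0-1 vector over the dataset's descriptors, or a
#'   character vector of descriptor names.
#' @param cv_groups number of deletion groups (default 5).
#' @param seed integer seed for the group shuffle.
#' @param n_repeats number of fold shuffles the Q2 is averaged over
#'   (default 1: a single split, the bare definition).
#' @return scalar fitness (at most 1; `-Inf` for subsets whose
#'   cross-validation designs are rank deficient).
#' @export
chromosome_fitness <- function(ds, genes, cv_groups = 5L, seed = 1L,
                               n_repeats = 1L) {
  stopifnot(inherits(ds, "qsar_dataset"))
  k <- length(ds$descriptor_names)
  if (is.character(genes)) genes <- ds$descriptor_names %in% genes
  genes <- as.logical(genes)
  if (length(genes) != k) {
    qsar_abort("genes must cover every candidate descriptor", "qsar_schema_error")
  }
  rows <- split_rows(ds, "train")
  nsel <- sum(genes)
  if (nsel < 1L || length(rows) <= nsel + 2L) {
    qsar_abort("chromosome selects too few or too many descriptors for the training size",
               "qsar_infeasible_chromosome_error")
  }
  seeds <- derive_seeds(seed, n_repeats)
  mean(vapply(seeds, function(s) {
    folds <- make_folds(length(rows), cv_groups, s)
    cv_q2_folds(ds$X[rows, , drop = FALSE], ds$y[rows], which(genes), folds)
  }, numeric(1L)))
}

# Force a chromosome into [1, max_vars] active genes by flipping random
# bits toward feasibility (indices drawn from the supplied RNG stream).
repair_chromosome <- function(genes, max_vars) {
  nsel <- sum(genes)
  if (nsel == 0L) {
    genes[sample.int(length(genes), 1L)] <- TRUE
  } else if (nsel > max_vars) {
    on_idx <- which(genes)
    genes[sample(on_idx, nsel - max_vars)] <- FALSE
  }
  genes
}

#' Genetic-algorithm descriptor selection
#'
#' Evolves a population of binary chromosomes (gene = descriptor
#' included/excluded) toward subsets with maximal cross-validated
#' explained variance. Generations use fitness-ranked binary-tournament
#' selection, uniform crossover, per-gene mutation, repair of chromosomes
#' violating the variable bounds, and single-elite carryover (so the best
#' selection score never decreases). The carried-over elite is refined by
#' a deterministic steepest single-flip local search — the memetic step
#' that sheds hitchhiking descriptors whose apparent contribution does
#' not survive the parsimony correction. The search stops at
#' `max_generations` or after `stagnation_generations` without
#' improvement. The whole run is a deterministic function of
#' `config$seed`.
#'
#' @param ds a [qsar_dataset()] that has been preprocessed (no constant
#'   descriptors, inter-correlation filtered); training rows are used.
#' @param config a [ga_config()].
#' @return object of class `ga_result`: list with `best_chromosome`
#'   (logical vector), `best_descriptors` (names), `best_fitness` (the
#'   cross-validated Q2 of the best chromosome), `fitness_trace` (best
#'   selection score per generation, element 1 = initial population;
#'   non-decreasing thanks to elitism), `selection_frequency` (named,
#'   fraction of the final population containing each descriptor),
#'   `generations_run`, `config`.
#' @export
ga_select <- function(ds, config = ga_config()) {
  stopifnot(inherits(ds, "qsar_dataset"), inherits(config, "ga_config"))
  rows <- split_rows(ds, "train")
  X <- ds$X[rows, , drop = FALSE]
  y <- ds$y[rows]
  n <- length(y)
  k <- ncol(X)
  max_vars <- min(config$max_variables, n - 3L)
  if (max_vars < 1L) qsar_abort("training set too small for any model", "qsar_config_error")
  fold_sets <- lapply(derive_seeds(config$seed, config$fitness_repeats),
                      function(s) make_folds(n, config$cv_groups, s))
  cache <- new.env(parent = emptyenv())
  q2_of <- function(genes) {
    key <- paste(which(genes), collapse = ",")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- mean(vapply(fold_sets, function(f) {
        cv_q2_folds(X, y, which(genes), f)
      }, numeric(1L)))
      cache[[key]] <- val
    }
    val
  }
  # Chromosomes compete on a parsimony-corrected score; reported fitness
  # stays the plain cross-validated Q2.
  fit_of <- function(genes) q2_of(genes) - config$parsimony_penalty * sum(genes)
  # Steepest-ascent single-flip refinement of a chromosome. Deterministic;
  # the fitness cache makes re-refining an unchanged elite free.
  local_improve <- function(genes) {
    repeat {
      cur <- fit_of(genes)
      nsel <- sum(genes)
      cand <- which(genes | rep(nsel < max_vars, k))
      scores <- vapply(cand, function(j) {
        g <- genes
        g[j] <- !g[j]
        if (sum(g) < 1L) -Inf else fit_of(g)
      }, numeric(1L))
      best <- which.max(scores)
      if (scores[best] <= cur + 1e-12) return(genes)
      genes[cand[best]] <- !genes[cand[best]]
    }
  }
  with_seed(config$seed, {
    pop <- lapply(seq_len(config$population_size), function(i) {
      repair_chromosome(stats::runif(k) < config$mean_initial_variables / k, max_vars)
    })
    fitness <- vapply(pop, fit_of, numeric(1L))
    trace <- max(fitness)
    stagnant <- 0L
    gen <- 0L
    while (gen < config$max_generations && stagnant < config$stagnation_generations) {
      gen <- gen + 1L
      elite <- local_improve(pop[[which.max(fitness)]])
      tournament <- function() {
        pair <- sample.int(config$population_size, 2L)
        pop[[pair[which.max(fitness[pair])]]]
      }
      newpop <- vector("list", config$population_size)
      newpop[[1L]] <- elite
      for (i in 2:config$population_size) {
        p1 <- tournament()
        child <- if (stats::runif(1L) < config$crossover_prob) {
          p2 <- tournament()
          mask <- stats::runif(k) < 0.5
          ifelse(mask, p1, p2)
        } else {
          p1
        }
        flip <- stats::runif(k) < config$mutation_prob
        child <- xor(child, flip)
        newpop[[i]] <- repair_chromosome(child, max_vars)
      }
      pop <- newpop
      fitness <- vapply(pop, fit_of, numeric(1L))
      best <- max(fitness)
      stagnant <- if (best > trace[length(trace)] + 1e-12) 0L else stagnant + 1L
      trace <- c(trace, best)
    }
    best_idx <- which.max(fitness)
    freq <- rowMeans(vapply(pop, as.numeric, numeric(k)))
    structure(list(best_chromosome = pop[[best_idx]],
                   best_descriptors = ds$descriptor_names[pop[[best_idx]]],
                   best_fitness = q2_of(pop[[best_idx]]),
                   fitness_trace = trace,
                   selection_frequency = stats::setNames(freq, ds$descriptor_names),
                   generations_run = gen,
                   config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best Q2_cv = %.4f after %d generations\n",
              x$best_fitness, x$generations_run))
  cat("  selected:", paste(x$best_descriptors, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a GA result to JSON
#' @param x a `ga_result`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
ga_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "ga_result"))
  obj <- list(best_descriptors = x$best_descriptors,
              best_chromosome = as.integer(x$best_chromosome),
              best_fitness = x$best_fitness,
              fitness_trace = x$fitness_trace,
              selection_frequency = as.list(x$selection_frequency),
              generations_run = x$generations_run,
              config = unclass(x$config))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Forward/backward stepwise descriptor selection
#'
#' Classical stepwise regression on partial-F p-values: at each step the
#' candidate whose addition gives the smallest p-value enters if that
#' p-value is below `enter_p`; after every entry, included descriptors
#' whose removal p-value exceeds `remove_p` are dropped (worst first).
#' Stops when no change occurs or `max_variables` is reached.
#'
#' @param ds a [qsar_dataset()]; training rows are used.
#' @param enter_p p-value below which a candidate enters (default 0.05).
#' @param remove_p p-value above which an included descriptor leaves
#'   (default 0.10); must exceed `enter_p`.
#' @param max_variables upper bound on the selected subset size.
#' @return character vector of selected descriptor names (possibly empty).
#' @export
stepwise_select <- function(ds, enter_p = 0.05, remove_p = 0.10,
                            max_variables = 30L) {
  stopifnot(inherits(ds, "qsar_dataset"))
  if (!(enter_p < remove_p)) {
    qsar_abort("enter_p must be smaller than remove_p", "qsar_config_error")
  }
  rows <- split_rows(ds, "train")
  X <- ds$X[rows, , drop = FALSE]
  y <- ds$y[rows]
  n <- length(y)
  k <- ncol(X)
  rss_of <- function(cols) {
    Xa <- cbind(1, X[, cols, drop = FALSE])
    qx <- qr(Xa)
    if (qx$rank < ncol(Xa)) return(NA_real_)
    sum(qr.resid(qx, y)^2)
  }
  partial_p <- function(rss_small, rss_big, df_resid_big) {
    if (is.na(rss_big) || rss_big <= 0 || df_resid_big < 1) return(NA_real_)
    f <- (rss_small - rss_big) / (rss_big / df_resid_big)
    stats::pf(f, 1, df_resid_big, lower.tail = FALSE)
  }
  selected <- integer(0)
  repeat {
    changed <- FALSE
    # forward step
    if (length(selected) < max_variables && n > length(selected) + 3L) {
      rss_cur <- rss_of(selected)
      cand <- setdiff(seq_len(k), selected)
      if (length(cand)) {
        df_big <- n - length(selected) - 2L
        pvals <- vapply(cand, function(j) {
          partial_p(rss_cur, rss_of(c(selected, j)), df_big)
        }, numeric(1L))
        ok <- which(!is.na(pvals))
        if (length(ok) && min(pvals[ok]) < enter_p) {
          selected <- c(selected, cand[ok[which.min(pvals[ok])]])
          changed <- TRUE
        }
      }
    }
    # backward step
    if (length(selected) > 0L) {
      repeat {
        rss_full <- rss_of(selected)
        df_full <- n - length(selected) - 1L
        pvals <- vapply(seq_along(selected), function(i) {
          partial_p(rss_of(selected[-i]), rss_full, df_full)
        }, numeric(1L))
        worst <- which.max(pvals)
        if (length(selected) && !is.na(pvals[worst]) && pvals[worst] > remove_p) {
          selected <- selected[-worst]
          changed <- TRUE
        } else break
        if (length(selected) == 0L) break
      }
    }
    if (!changed) break
  }
  ds$descriptor_names[selected]
}
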