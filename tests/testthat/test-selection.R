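test_that("chromosome fitness is the cross-validated Q2 of the encoded subset", {
  # noiseless linear data: perfect out-of-fold prediction
  pr <- rand_problem(20, 3, seed = 2, noise = 0)
  ds <- qsar_dataset(pr$X, pr$y)
  expect_equal(chromosome_fitness(ds, c(TRUE, TRUE, TRUE), seed = 1), 1,
               tolerance = 1e-10)
  # identical subsets, identical seed -> identical fitness
  f1 <- chromosome_fitness(ds, c(TRUE, FALSE, TRUE), seed = 5)
  f2 <- chromosome_fitness(ds, colnames(pr$X)[c(1, 3)], seed = 5)
  expect_identical(f1, f2)
  expect_error(chromosome_fitness(ds, rep(FALSE, 3)),
               class = "qsar_infeasible_chromosome_error")
})

test_that("pure-noise responses give non-positive fitness in most replicates", {
  set.seed(55)
  neg <- replicate(200, {
    X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("d", 1:4)))
    ds <- qsar_dataset(X, rnorm(30))
    chromosome_fitness(ds, rep(TRUE, 4), seed = 1) <= 0
  })
  expect_gte(mean(neg), 0.75)
})

test_that("ga runs are reproducible, elitist-monotone, and size-stable", {
  ds <- generate_qsar(benchmark_spec(seed = 9))
  cfg <- ga_config(seed = 4, max_generations = 15, stagnation_generations = 10)
  r1 <- ga_select(ds, cfg)
  r2 <- ga_select(ds, cfg)
  expect_identical(r1[names(r1) != "config"], r2[names(r2) != "config"])
  expect_true(all(diff(r1$fitness_trace) >= -1e-12))
  expect_equal(length(r1$selection_frequency), 50)
  expect_true(all(r1$selection_frequency >= 0 & r1$selection_frequency <= 1))
  expect_lte(sum(r1$best_chromosome), cfg$max_variables)
  expect_gte(sum(r1$best_chromosome), 1)

  # zero generations: best of the initial random population
  r0 <- ga_select(ds, ga_config(seed = 4, max_generations = 0))
  expect_equal(r0$generations_run, 0L)
  expect_equal(length(r0$fitness_trace), 1L)

  js <- jsonlite::fromJSON(ga_result_json(r1))
  expect_equal(js$best_descriptors, r1$best_descriptors)
  expect_equal(length(js$fitness_trace), length(r1$fitness_trace))
})

test_that("ga recovers an informative subset on an easy benchmark", {
  # strong signal, modest pool: the selected model must contain the
  # dominant true descriptors and fit well out-of-fold
  spec <- synthetic_spec(36, 20, 0.2, true_support = c(3L, 9L, 15L),
                         true_coefficients = c(2, -2, 2.5),
                         noise_sd = 0.4, seed = 300)
  ds <- generate_qsar(spec)
  r <- ga_select(ds, ga_config(seed = 1, max_generations = 40))
  expect_gte(r$best_fitness, 0.8)
  truth <- attr(ds, "truth")$support_names
  expect_gte(length(intersect(r$best_descriptors, truth)), 2)
})

test_that("ga selection frequencies favour true over noise descriptors", {
  hits <- vapply(1:6, function(s) {
    ds <- generate_qsar(benchmark_spec(seed = 600 + s))
    truth <- attr(ds, "truth")$support_names
    r <- ga_select(ds, ga_config(seed = s, max_generations = 60))
    mean(r$selection_frequency[truth]) >
      mean(r$selection_frequency[setdiff(names(r$selection_frequency), truth)])
  }, logical(1))
  expect_gte(mean(hits), 5 / 6)
})

test_that("ga config validates and loads from YAML/JSON", {
  expect_error(ga_config(mutation_prob = 0), class = "qsar_config_error")
  expect_error(ga_config(crossover_prob = 1.5), class = "qsar_config_error")
  expect_error(ga_config(cv_groups = 1), class = "qsar_config_error")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("population_size: 20", "mutation_prob: 0.05", "seed: 77"), path)
  cfg <- read_ga_config(path)
  expect_equal(cfg$population_size, 20L)
  expect_equal(cfg$mutation_prob, 0.05)
  expect_equal(cfg$crossover_prob, 0.5)   # default retained
  writeLines(c("poplation_size: 20"), path)
  expect_error(read_ga_config(path), class = "qsar_config_error")
})

test_that("stepwise selection finds signal, resists noise, and obeys bounds", {
  # one perfectly predictive descriptor among noise enters first
  set.seed(12)
  X <- matrix(rnorm(36 * 8), 36, 8, dimnames = list(NULL, paste0("d", 1:8)))
  y <- 2 + 3 * X[, 5] + rnorm(36, sd = 0.05)
  ds <- qsar_dataset(X, y)
  sel <- stepwise_select(ds)
  expect_true("d5" %in% sel)
  expect_equal(sel[1], "d5")

  # pure noise with a strict entry threshold: near-empty selections
  set.seed(200)
  sizes <- replicate(20, {
    Xn <- matrix(rnorm(36 * 20), 36, 20, dimnames = list(NULL, paste0("n", 1:20)))
    length(stepwise_select(qsar_dataset(Xn, rnorm(36)), enter_p = 0.001))
  })
  expect_gte(mean(sizes == 0), 0.8)

  # bound enforcement
  expect_lte(length(stepwise_select(ds, max_variables = 1)), 1)
  expect_error(stepwise_select(ds, enter_p = 0.2, remove_p = 0.1),
               class = "qsar_config_error")
})
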