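test_that("q2_loo shortcut equals explicit leave-one-out refits", {
  for (seed in 1:30) {
    n <- sample(12:40, 1)
    k <- sample(1:6, 1)
    pr <- rand_problem(n, k, seed = 300 + seed)
    expect_equal(q2_loo(pr$X, pr$y), q2_loo_oracle(pr$X, pr$y),
                 tolerance = 1e-10)
  }
})

test_that("q2_loo is 1 for noiseless data and below R2_train in general", {
  pr <- rand_problem(20, 3, seed = 1, noise = 0)
  expect_equal(q2_loo(pr$X, pr$y), 1, tolerance = 1e-10)
  for (seed in c(11, 22, 33, 44)) {
    pr <- rand_problem(24, 4, seed = seed)
    m <- fit_ols(pr$X, pr$y)
    r2 <- model_statistics(m, pr$X, pr$y, "train")$r2
    expect_lte(q2_loo(pr$X, pr$y), r2)
  }
})

test_that("permuted responses give negative q2_loo in the large majority of cases", {
  set.seed(404)
  pr <- rand_problem(29, 5, seed = 77, noise = 0.3)
  neg <- mean(replicate(100, q2_loo(pr$X, sample(pr$y)) < 0))
  expect_gte(neg, 0.8)
})

test_that("leave-group-out degenerates to LOO and honours its seed", {
  pr <- rand_problem(18, 3, seed = 5)
  # one compound per deletion group, enough repeats irrelevant: every
  # partition covers each point exactly once
  lgo <- q2_lgo(pr$X, pr$y, group_fraction = 1 / 18, n_repeats = 1, seed = 3)
  expect_equal(lgo, q2_loo(pr$X, pr$y), tolerance = 1e-10)

  pr0 <- rand_problem(18, 3, seed = 6, noise = 0)
  expect_equal(q2_lgo(pr0$X, pr0$y, 0.2, 10, seed = 1), 1, tolerance = 1e-10)

  a <- q2_lgo(pr$X, pr$y, 0.2, 25, seed = 9)
  b <- q2_lgo(pr$X, pr$y, 0.2, 25, seed = 9)
  d <- q2_lgo(pr$X, pr$y, 0.2, 25, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, d))
  expect_error(q2_lgo(pr$X, pr$y, 0.9, 5, 1), class = "qsar_config_error")
})

test_that("bootstrap q2 is deterministic under seed and exact for noiseless data", {
  pr0 <- rand_problem(20, 3, seed = 2, noise = 0)
  expect_equal(as.numeric(q2_boot(pr0$X, pr0$y, n_boot = 50, seed = 1)), 1,
               tolerance = 1e-8)
  pr <- rand_problem(25, 4, seed = 3)
  a <- q2_boot(pr$X, pr$y, n_boot = 200, seed = 7)
  b <- q2_boot(pr$X, pr$y, n_boot = 200, seed = 7)
  expect_identical(a, b)
  expect_lte(as.numeric(a), 1)
  expect_gte(attr(a, "skipped"), 0L)
})

test_that("y_randomization permutes the response and records chance-level fits", {
  pr <- rand_problem(29, 5, seed = 8, noise = 0.3)
  yr <- y_randomization(pr$X, pr$y, n_iterations = 10, seed = 42)
  expect_equal(nrow(yr$iterations), 10)
  expect_identical(y_randomization(pr$X, pr$y, 10, seed = 42)$iterations,
                   yr$iterations)
  # informative original data towers over the permuted refits
  m <- fit_ols(pr$X, pr$y)
  r2_orig <- model_statistics(m, pr$X, pr$y, "train")$r2
  expect_gt(r2_orig, max(yr$iterations$r2))
  expect_gt(q2_loo(pr$X, pr$y), max(yr$iterations$q2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_y_randomization(yr, path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("No", "Q2", "R2"))
  expect_equal(tab$Q2, yr$iterations$q2)
})

test_that("external validation computes test-set R2 and RMSE and flags degenerates", {
  pr <- rand_problem(30, 3, seed = 9)
  ds <- qsar_dataset(pr$X, pr$y, split = rep(c("train", "test"), c(22, 8)))
  m <- fit_qsar(ds)
  ev <- external_validation(m, ds)
  idx <- 23:30
  pred <- predict(m, pr$X[idx, ])
  expect_equal(ev$rmse_test, sqrt(mean((pr$y[idx] - pred)^2)), tolerance = 1e-12)
  expect_equal(ev$r2_test,
               1 - sum((pr$y[idx] - pred)^2) / sum((pr$y[idx] - mean(pr$y[idx]))^2),
               tolerance = 1e-12)

  # noiseless test rows drawn from the model itself
  ds2 <- ds; ds2$y[idx] <- pred
  ev2 <- external_validation(m, ds2)
  expect_equal(ev2$r2_test, 1, tolerance = 1e-10)
  expect_equal(ev2$rmse_test, 0, tolerance = 1e-10)

  # single test compound: RMSE = |residual|, R2 undefined
  ds3 <- qsar_dataset(pr$X, pr$y, split = c(rep("train", 29), "test"))
  m3 <- fit_qsar(ds3)
  expect_warning(ev3 <- external_validation(m3, ds3), "undefined")
  expect_true(is.na(ev3$r2_test))
  expect_equal(ev3$rmse_test, abs(pr$y[30] - predict(m3, pr$X[30, , drop = FALSE])))
  expect_error(external_validation(m, qsar_dataset(pr$X, pr$y)),
               class = "qsar_config_error")
})

test_that("a mean-only style model scores non-positive R2 on centered test data", {
  set.seed(15)
  ok <- 0
  for (r in 1:20) {
    X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
    y <- rnorm(20)                       # y unrelated to X
    ds <- qsar_dataset(X, y, split = rep(c("train", "test"), each = 10))
    m <- fit_qsar(ds)
    ev <- suppressWarnings(external_validation(m, ds))
    if (!is.na(ev$r2_test) && ev$r2_test <= 0) ok <- ok + 1
  }
  expect_gte(ok, 14)
})

test_that("the bundled validation battery is reproducible and coherent", {
  ds <- split_train_test(rand_dataset(36, 5, seed = 123), 0.2, seed = 1)
  m <- fit_qsar(ds)
  v1 <- validate_model(m, ds, n_boot = 300, seed = 10)
  v2 <- validate_model(m, ds, n_boot = 300, seed = 10)
  expect_identical(unclass(v1), unclass(v2))
  expect_lte(v1$q2_loo, 1)
  expect_lte(v1$q2_lgo, 1)
  expect_lte(v1$q2_boot, 1)
})
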