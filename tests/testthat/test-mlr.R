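test_that("exact linear data is interpolated and constant y gives zero slope", {
  x <- matrix(seq_len(8), 8, 1, dimnames = list(NULL, "x"))
  m <- fit_ols(x, 1 + 2 * x[, 1])
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-10)
  expect_equal(m$rmse_train, 0, tolerance = 1e-10)

  set.seed(1)
  x2 <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "x"))
  m2 <- fit_ols(x2, rep(4.2, 10))
  expect_equal(unname(m2$coefficients), 0, tolerance = 1e-10)
  expect_equal(m2$intercept, 4.2, tolerance = 1e-10)
})

test_that("fit_ols agrees with a normal-equations oracle on many random instances", {
  for (seed in 1:100) {
    n <- sample(8:30, 1)
    k <- sample(1:5, 1)
    pr <- rand_problem(n, k, seed = seed)
    m <- fit_ols(pr$X, pr$y)
    expect_equal(unname(c(m$intercept, m$coefficients)),
                 unname(ols_oracle(pr$X, pr$y)), tolerance = 1e-10)
  }
})

test_that("standard errors match the conventional OLS estimates", {
  pr <- rand_problem(25, 3, seed = 99)
  m <- fit_ols(pr$X, pr$y)
  fit <- lm(pr$y ~ pr$X)
  expect_equal(unname(m$coef_std_errors),
               unname(summary(fit)$coefficients[, "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(m$sigma, summary(fit)$sigma, tolerance = 1e-10)
})

test_that("rank deficiency and sample-size violations are rejected", {
  set.seed(3)
  x <- rnorm(10)
  X <- cbind(a = x, b = 2 * x, c = rnorm(10))
  err <- expect_error(fit_ols(X, rnorm(10)), class = "qsar_singular_design_error")
  expect_match(conditionMessage(err), "[ab]")
  expect_error(fit_ols(matrix(rnorm(8), 2, 4), rnorm(2)),
               class = "qsar_sample_size_error")
})

test_that("predictions follow the linear form and respect column naming", {
  pr <- rand_problem(20, 3, seed = 12)
  m <- fit_ols(pr$X, pr$y)
  # zero mean residual on the training design (normal equations)
  expect_equal(mean(pr$y - predict(m, pr$X)), 0, tolerance = 1e-10)
  # all-zero row predicts the intercept
  z <- matrix(0, 1, 3, dimnames = list(NULL, colnames(pr$X)))
  expect_equal(predict(m, z), m$intercept)
  # shuffled columns are matched by name
  perm <- pr$X[, c(3, 1, 2)]
  expect_equal(predict(m, perm), predict(m, pr$X))
  # duplicated row gives identical predictions
  two <- pr$X[c(4, 4), ]
  expect_equal(predict(m, two)[1], predict(m, two)[2])
  bad <- pr$X; colnames(bad) <- c("d1", "zzz", "d3")
  expect_error(predict(m, bad), class = "qsar_schema_error")
})

test_that("statistics block matches its defining formulas", {
  pr <- rand_problem(29, 5, seed = 7)
  m <- fit_ols(pr$X, pr$y)
  st <- model_statistics(m, pr$X, pr$y, "train")
  rss <- sum((pr$y - predict(m, pr$X))^2)
  tss <- sum((pr$y - mean(pr$y))^2)
  r2 <- 1 - rss / tss
  expect_equal(st$r2, r2, tolerance = 1e-12)
  expect_equal(st$r2_adj, 1 - (1 - r2) * 28 / 23, tolerance = 1e-12)
  expect_equal(st$f_stat, (r2 / 5) / ((1 - r2) / 23), tolerance = 1e-12)
  expect_equal(st$rmse, sqrt(rss / 29), tolerance = 1e-12)
  expect_lte(st$r2_adj, st$r2)
  # worked arithmetic: k = 5, n = 29, R2 = 0.86 -> R2_adj = 1 - 0.14*28/23
  expect_equal(1 - (1 - 0.86) * 28 / 23, 0.8295652, tolerance = 1e-6)

  # perfect fit
  yhat <- predict(m, pr$X)
  stp <- model_statistics(m, pr$X, yhat, "train")
  expect_equal(stp$rmse, 0, tolerance = 1e-8)

  expect_error(model_statistics(m, pr$X, rep(1, 29), "test"),
               class = "qsar_undefined_stat_error")
})

test_that("adding a descriptor never decreases training R2", {
  for (seed in c(2, 9, 31)) {
    pr <- rand_problem(25, 6, seed = seed)
    r2 <- vapply(1:6, function(k) {
      m <- fit_ols(pr$X[, 1:k, drop = FALSE], pr$y)
      model_statistics(m, pr$X[, 1:k, drop = FALSE], pr$y, "train")$r2
    }, numeric(1))
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("the model serializes to JSON and the equation renders with SEs", {
  pr <- rand_problem(15, 2, seed = 4)
  m <- fit_ols(pr$X, pr$y)
  parsed <- jsonlite::fromJSON(model_json(m))
  expect_equal(parsed$intercept, m$intercept)
  expect_equal(unlist(parsed$coefficients), m$coefficients)
  eq <- format_equation(m)
  expect_match(eq, "^pIC50 = ")
  expect_match(eq, "d1")
  expect_match(eq, "\\(")   # standard errors in parentheses
})
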