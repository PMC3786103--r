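test_that("leverage matches the brute-force hat diagonal and its identities", {
  for (seed in c(4, 18, 52)) {
    pr <- rand_problem(12, 3, seed = seed)
    m <- fit_ols(pr$X, pr$y)
    h <- leverage(m, pr$X)
    expect_equal(h, leverage_oracle(pr$X), tolerance = 1e-10)
    expect_equal(sum(h), 4, tolerance = 1e-8)       # trace of hat = p
    expect_true(all(h >= 1 / 12 - 1e-12 & h <= 1 + 1e-12))
  }
  # a row equal to the mean of the others sits at the overall centroid,
  # whose leverage is exactly 1/n
  set.seed(31)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  X[10, ] <- colMeans(X[1:9, ])
  m <- fit_ols(X, rnorm(10))
  h <- leverage(m, X)
  expect_equal(h[10], 1 / 10, tolerance = 1e-10)
})

test_that("warning leverage is 3p/n", {
  expect_equal(warning_leverage(29, 6), 18 / 29)
  expect_equal(warning_leverage(29, 6), 0.620690, tolerance = 1e-6)
  expect_equal(warning_leverage(18, 6), 1)
  expect_equal(warning_leverage(30, 1), 0.1)
  expect_error(warning_leverage(0, 3), class = "qsar_config_error")
})

test_that("williams classification flags leverage and residual violations", {
  pr <- rand_problem(25, 3, seed = 44, noise = 0.4)
  ds <- qsar_dataset(pr$X, pr$y, split = rep("train", 25))
  m <- fit_qsar(ds)

  # an extreme test compound far outside the training cloud is high leverage
  far <- matrix(10 * apply(pr$X, 2, sd), 1, 3) + colMeans(pr$X)
  colnames(far) <- colnames(pr$X)
  X2 <- rbind(pr$X, far)
  y2 <- c(pr$y, predict(m, far))
  ds2 <- qsar_dataset(X2, y2, split = c(rep("train", 25), "test"))
  rep2 <- williams_classify(m, ds2)
  expect_equal(rep2$warning_leverage, 3 * 4 / 25)
  expect_gt(rep2$table$leverage[26], rep2$warning_leverage)
  expect_true(rep2$table$flag[26] %in% c("high_leverage", "both"))

  # infinite cutoff disables outlier flags
  rep3 <- williams_classify(m, ds2, residual_cutoff = Inf)
  expect_false(any(rep3$table$flag %in% c("outlier", "both")))

  # noiseless fit: all standardized residuals 0
  pr0 <- rand_problem(15, 2, seed = 3, noise = 0)
  ds0 <- qsar_dataset(pr0$X, pr0$y)
  m0 <- fit_qsar(ds0)
  rep0 <- williams_classify(m0, ds0)
  expect_equal(rep0$table$std_residual, rep(0, 15), tolerance = 1e-6)
  expect_true(all(rep0$table$flag %in% c("in_domain", "high_leverage")))
})

test_that("williams flags are invariant to affine rescaling of the activity", {
  pr <- rand_problem(30, 4, seed = 90)
  ds <- qsar_dataset(pr$X, pr$y, split = rep(c("train", "test"), c(24, 6)))
  m <- fit_qsar(ds)
  f1 <- williams_classify(m, ds)
  ds2 <- ds; ds2$y <- 3 * ds$y - 7
  m2 <- fit_qsar(ds2)
  f2 <- williams_classify(m2, ds2)
  expect_equal(f2$table$flag, f1$table$flag)
  expect_equal(f2$table$leverage, f1$table$leverage, tolerance = 1e-10)
  expect_equal(f2$table$std_residual, f1$table$std_residual, tolerance = 1e-8)
})

test_that("williams report writes plot-ready data with threshold metadata", {
  pr <- rand_problem(20, 2, seed = 6)
  ds <- qsar_dataset(pr$X, pr$y)
  m <- fit_qsar(ds)
  rp <- williams_classify(m, ds)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_williams(rp, path)
  lines <- readLines(path)
  expect_match(lines[1], "warning_leverage")
  tab <- read.delim(path, comment.char = "#")
  expect_equal(nrow(tab), 20)
  expect_equal(names(tab), c("compound", "split", "leverage", "std_residual", "flag"))
})

test_that("VIF closed forms and oracle agreement hold", {
  expect_equal(unname(vif_from_correlation(diag(4))), rep(1, 4))
  R2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  expect_equal(unname(vif_from_correlation(R2)), rep(1 / (1 - 0.36), 2),
               tolerance = 1e-12)
  # VIF grows monotonically as a pair's correlation approaches 1
  vifs <- vapply(c(0.1, 0.5, 0.9, 0.99), function(r) {
    vif_from_correlation(matrix(c(1, r, r, 1), 2, 2))[1]
  }, numeric(1))
  expect_true(all(diff(vifs) > 0))

  for (seed in c(7, 23, 61)) {
    pr <- rand_problem(40, 5, seed = seed)
    expect_equal(unname(vif_from_data(pr$X)), vif_oracle(pr$X), tolerance = 1e-9)
  }
  # near-duplicated column explodes its VIF
  set.seed(2)
  a <- rnorm(60)
  X <- cbind(a = a, b = a + rnorm(60, sd = 0.02), c = rnorm(60))
  v <- vif_from_data(X)
  expect_gt(v["a"], 100)
  expect_equal(unname(v), vif_oracle(X), tolerance = 1e-6)

  sing <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_error(vif_from_correlation(sing), class = "qsar_singular_collinearity_error")
  expect_error(vif_from_correlation(matrix(c(1, 0.2, 0.4, 1), 2, 2)),
               class = "qsar_config_error")
})

test_that("collinearity report carries matrix, VIFs and advisory bands", {
  pr <- rand_problem(30, 4, seed = 13)
  cr <- collinearity_report(pr$X)
  expect_equal(diag(cr$correlation_matrix), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(cr$vif >= 1 - 1e-10))
  expect_true(all(cr$vif_band %in%
                  c("no inter-correlation", "acceptable", "borderline", "unstable")))
})

test_that("mean effects sum to one, ignore the intercept, and are scale-coherent", {
  pr <- rand_problem(22, 4, seed = 17, intercept = 3)
  pr$X <- pr$X + 2          # keep descriptor sums away from zero
  m <- fit_ols(pr$X, pr$y)
  mf <- mean_effects(m, pr$X)
  expect_equal(sum(mf$mean_effects), 1, tolerance = 1e-9)
  expect_identical(mf$intercept_effect, 0)
  # manual recomputation of the defining ratio
  terms <- m$coefficients * colSums(pr$X)
  expect_equal(unname(mf$mean_effects), unname(terms / sum(terms)), tolerance = 1e-12)

  # single-descriptor model: MF = 1
  m1 <- fit_ols(pr$X[, 1, drop = FALSE], pr$y)
  expect_equal(unname(mean_effects(m1, pr$X[, 1, drop = FALSE])$mean_effects), 1)

  # doubling descriptors while halving coefficients leaves MF unchanged
  m2 <- m
  m2$coefficients <- m$coefficients / 2
  mf2 <- mean_effects(m2, 2 * pr$X)
  expect_equal(mf2$mean_effects, mf$mean_effects, tolerance = 1e-12)

  # cancelling denominator is rejected
  m3 <- m
  m3$coefficients[] <- 0
  expect_error(mean_effects(m3, pr$X), class = "qsar_undefined_mean_effect_error")
})
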