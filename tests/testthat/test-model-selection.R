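test_that("equation enumeration honors size and collinearity bans", {
  cand <- c("a", "b", "c", "d")
  cc <- diag(4); dimnames(cc) <- list(cand, cand)
  expect_length(enumerate_equations(cand, cc), 14)      # 4 + 6 + 4
  cc2 <- cc; cc2["a", "b"] <- cc2["b", "a"] <- 0.9
  expect_length(enumerate_equations(cand, cc2), 11)     # minus {ab} supersets
  expect_length(enumerate_equations("a", matrix(1, 1, 1,
                                                dimnames = list("a", "a"))), 1)
  sets <- enumerate_equations(cand, cc2)
  expect_false(any(vapply(sets, function(s) all(c("a", "b") %in% s), TRUE)))
})

test_that("correlated-candidate pruning keeps the better single-term model", {
  set.seed(40)
  n <- 60
  a <- rnorm(n)
  b <- a + rnorm(n, 0, 0.2)      # r ~ 0.98 with a, noisier fit to y
  c0 <- rnorm(n)
  X <- cbind(a = a, b = b, c = c0)
  y <- a + rnorm(n, 0, 0.3)
  folds <- make_cv_folds(n, 5, 5, seed = 1)
  kept <- prune_correlated_candidates(c("a", "b", "c"), X, y, 0.85, folds)
  expect_setequal(kept, c("a", "c"))
  # no correlated pairs: unchanged
  expect_equal(prune_correlated_candidates(c("a", "c"), X, y, 0.85, folds),
               c("a", "c"))
  # a ~ b ~ c chain resolves deterministically
  X2 <- cbind(a = a, b = a + rnorm(n, 0, 0.15), c = a + rnorm(n, 0, 0.25))
  k1 <- prune_correlated_candidates(c("a", "b", "c"), X2, y, 0.85, folds)
  k2 <- prune_correlated_candidates(c("a", "b", "c"), X2, y, 0.85, folds)
  expect_identical(k1, k2)
  expect_lt(length(k1), 3)
})

test_that("cross-validated MSE has the expected extremes and is fold-deterministic", {
  set.seed(41)
  X <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("a", "b")))
  y <- 2 * X[, "a"] - X[, "b"]
  folds <- make_cv_folds(60, 5, 5, seed = 2)
  expect_lt(cv_mse(c("a", "b"), X, y, folds)$mse, 1e-20)
  # null model on centered noise approximates var(y)
  y2 <- rnorm(60); y2 <- y2 - mean(y2)
  m0 <- cv_mse(character(0), X, y2, folds)
  expect_lt(abs(m0$mse - mean(y2^2)) / mean(y2^2), 1e-12)
  expect_length(m0$resid2, 60 * 5)
  f2 <- make_cv_folds(60, 5, 5, seed = 2)
  expect_identical(cv_mse("a", X, y2, folds), cv_mse("a", X, y2, f2))
})

test_that("folds are stratified so every fold spans all strata", {
  strata <- rep(c("A", "B", "C", "D"), each = 15)
  folds <- make_cv_folds(60, 5, 3, strata, seed = 3)
  for (f in folds)
    for (k in 1:5)
      expect_setequal(unique(strata[f == k]), c("A", "B", "C", "D"))
  expect_error(make_cv_folds(3, 5, 1), "at least as many")
})

test_that("BIC follows n*ln(mse) + p*ln(n)", {
  expect_equal(bic(1, 60, 0), 0)
  expect_equal(bic(0.25, 60, 3), 60 * log(0.25) + 3 * log(60))
  expect_lt(bic(0.3, 60, 2), bic(0.3, 60, 3))
  # adding a term only wins if the MSE improves more than the penalty factor
  expect_gt(bic(0.3 * exp(-log(60) / 60) * 1.01, 60, 3), bic(0.3, 60, 2))
  expect_lt(bic(0.3 * exp(-log(60) / 60) * 0.99, 60, 3), bic(0.3, 60, 2))
})

test_that("composite MSE is the size-weighted pooling of segment MSEs", {
  r1 <- rep(0.1, 30 * 5); r2 <- rep(0.3, 30 * 5)
  expect_equal(composite_mse(list(r1, r2)), 0.2, tolerance = 1e-12)
  expect_equal(composite_mse(list(r1)), 0.1, tolerance = 1e-12)
  r3 <- rep(0.4, 15 * 5); r4 <- rep(0, 45 * 5)
  expect_equal(composite_mse(list(r3, r4)), 0.1, tolerance = 1e-12)
  # identity against arbitrary random partitions
  set.seed(44)
  for (i in 1:10) {
    parts <- split(runif(100), sample(1:4, 100, replace = TRUE))
    lhs <- composite_mse(parts)
    rhs <- sum(vapply(parts, sum, 0)) / 100
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("select_equation matches brute-force enumeration with shared folds", {
  f <- fx()
  cfg <- selection_config()
  for (s in 1:20) {
    set.seed(800 + s)
    cand <- sample(colnames(f$X), sample(3:10, 1))
    beta <- c(1, -0.8)
    y <- as.numeric(f$X[, sample(cand, 2)] %*% beta) + rnorm(60, 0, 0.5)
    folds <- make_cv_folds(60, 5, 5, seed = s)
    eq <- select_equation(f$X, y, cand, cfg, fold_assignments = folds)
    want <- brute_force_equation(f$X, y, cand, cfg, folds)
    expect_setequal(eq$params, want)
  }
})

test_that("select_equation finds strong truths and nulls out pure noise", {
  f <- fx()
  cfg <- selection_config()
  exact <- 0
  for (s in 1:10) {
    set.seed(900 + s)
    y <- 0.8 * f$X[, "tp_e4hr"] + rnorm(60, 0, 0.4)
    eq <- select_equation(f$X, y, c("tp_e4hr", "hu_3d", "ra_15d", "wd_d2hr"),
                          cfg, seed = s)
    exact <- exact + identical(eq$params, "tp_e4hr")
  }
  expect_gte(exact, 8)
  nulls <- 0
  for (s in 1:20) {
    set.seed(950 + s)
    y <- rnorm(60)
    cand <- sample(colnames(f$X), 5)
    eq <- select_equation(f$X, y, cand, cfg, seed = s)
    nulls <- nulls + (length(eq$params) == 0)
  }
  expect_gte(nulls / 20, 0.8)
})

test_that("fitted coefficients land near the generating values", {
  f <- fx()
  cfg <- selection_config()
  set.seed(60)
  y <- 0.7 * f$X[, "tp_d2hr"] - 0.6 * f$X[, "sm15"] + rnorm(60, 0, 0.3)
  eq <- select_equation(f$X, y, c("tp_d2hr", "sm15", "hu_3d"), cfg, seed = 1)
  expect_setequal(eq$params, c("tp_d2hr", "sm15"))
  fit <- lm(y ~ 0 + f$X[, "tp_d2hr"] + f$X[, "sm15"])
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(eq$coef["tp_d2hr"] - 0.7), 3 * se[1])
  expect_lt(abs(eq$coef["sm15"] + 0.6), 3 * se[2])
  expect_gt(eq$r2, 0.5)
})
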