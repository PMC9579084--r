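test_that("two-way mixed ICC matches a from-scratch ANOVA oracle on random instances", {
  icc_oracle <- function(X, type, definition) {
    # scalar-loop two-way ANOVA mean squares
    n <- nrow(X); k <- ncol(X)
    gm <- mean(X)
    msr <- 0; msc <- 0; sse <- 0
    rm_ <- rowMeans(X); cm_ <- colMeans(X)
    for (i in 1:n) msr <- msr + k * (rm_[i] - gm)^2
    msr <- msr / (n - 1)
    for (j in 1:k) msc <- msc + n * (cm_[j] - gm)^2
    msc <- msc / (k - 1)
    for (i in 1:n) for (j in 1:k)
      sse <- sse + (X[i, j] - rm_[i] - cm_[j] + gm)^2
    mse <- sse / ((n - 1) * (k - 1))
    if (definition == "consistency") {
      if (type == "single") (msr - mse) / (msr + (k - 1) * mse)
      else (msr - mse) / msr
    } else {
      if (type == "single")
        (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
      else (msr - mse) / (msr + (msc - mse) / n)
    }
  }
  set.seed(31)
  for (r in 1:100) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    ty <- sample(c("single", "average"), 1)
    df <- sample(c("consistency", "agreement"), 1)
    expect_equal(icc_two_way_mixed(X, ty, df)$icc,
                 icc_oracle(X, ty, df), tolerance = 1e-12)
  }
})

test_that("ICC definitions distinguish identical from shifted raters", {
  set.seed(2)
  r1 <- rnorm(20)
  X_same <- cbind(r1, r1)
  expect_equal(icc_two_way_mixed(X_same, "single", "consistency")$icc, 1,
               tolerance = 1e-12)
  X_shift <- cbind(r1, r1 + 0.8)
  expect_equal(icc_two_way_mixed(X_shift, "single", "consistency")$icc, 1,
               tolerance = 1e-12)
  expect_lt(icc_two_way_mixed(X_shift, "single", "agreement")$icc, 1)
  # zero between-target variance is undefined
  expect_error(icc_two_way_mixed(cbind(rep(1, 5), rep(2, 5))), "undefined")
})

test_that("paired contrast matches textbook formulas and is antisymmetric", {
  set.seed(5)
  x <- rnorm(30, 1); y <- rnorm(30)
  pc <- paired_contrast(x, y)
  # scalar-loop oracle
  d <- x - y
  md <- sum(d) / 30
  sdd <- sqrt(sum((d - md)^2) / 29)
  t_o <- md / (sdd / sqrt(30))
  expect_equal(pc$t, t_o, tolerance = 1e-12)
  expect_equal(pc$cohens_d, md / sdd, tolerance = 1e-12)
  expect_equal(pc$p, 2 * pt(abs(t_o), 29, lower.tail = FALSE),
               tolerance = 1e-12)
  pc_rev <- paired_contrast(y, x)
  expect_equal(pc_rev$t, -pc$t, tolerance = 1e-12)
  expect_equal(pc_rev$cohens_d, -pc$cohens_d, tolerance = 1e-12)
  # identical samples: t = d = 0
  pc0 <- paired_contrast(x, x)
  expect_equal(pc0$t, 0)
  expect_equal(pc0$cohens_d, 0)
  # constant nonzero difference is degenerate
  expect_error(paired_contrast(x, x + 1), "zero variance")
})

test_that("parallel analysis retains the right counts on noise and factor data", {
  # trace identity: PCA eigenvalues of a correlation matrix sum to p
  set.seed(41)
  X <- matrix(rnorm(200 * 8), 200, 8)
  pa <- parallel_analysis(X, n_sims = 30, seed = 1)
  expect_equal(sum(pa$pc_eigenvalues), 8, tolerance = 1e-10)
  expect_true(all(diff(pa$pc_eigenvalues) <= 1e-12))
  # pure noise retains ~0 factors (10 seeded runs, allow one failure)
  hits <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(500 * 10), 500, 10)
    if (parallel_analysis(Xn, n_sims = 40, seed = s)$n_factors_retained == 0)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  # 3-factor data (salient loadings .7, n = 500) retains 3
  L <- matrix(0, 9, 3); L[1:3, 1] <- L[4:6, 2] <- L[7:9, 3] <- 0.7
  hits <- 0L
  for (s in 1:10) {
    set.seed(200 + s)
    FS <- matrix(rnorm(500 * 3), 500, 3)
    X3 <- FS %*% t(L) +
      matrix(rnorm(500 * 9), 500, 9) %*% diag(sqrt(1 - rowSums(L^2)))
    if (parallel_analysis(X3, n_sims = 40, seed = s)$n_factors_retained == 3)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  expect_error(parallel_analysis(cbind(rep(1, 50), rnorm(50))), "constant")
})

test_that("EFA recovers planted simple structure and is scale-invariant", {
  set.seed(51)
  L <- cbind(c(rep(0.8, 4), rep(0, 4)), c(rep(0, 4), rep(0.8, 4)))
  FS <- matrix(rnorm(1000 * 2), 1000, 2)
  X <- FS %*% t(L) +
    matrix(rnorm(1000 * 8), 1000, 8) %*% diag(sqrt(1 - rowSums(L^2)))
  ef <- efa(X, 2, rotation = "oblimin", estimator = "ml")
  expect_true(all(tucker_congruence(L, ef$loadings) > 0.95))
  expect_equal(diag(ef$Phi), c(1, 1), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(isSymmetric(ef$Phi, tol = 1e-10))
  # loadings invariant to variable rescaling
  X_resc <- X %*% diag(c(10, 0.1, 1, 5, 2, 0.5, 1, 3))
  ef2 <- efa(X_resc, 2, rotation = "oblimin", estimator = "ml")
  expect_equal(abs(ef2$loadings), abs(ef$loadings), tolerance = 1e-6,
               ignore_attr = TRUE)
  # minres extraction agrees with ML here
  ef3 <- efa(X, 2, rotation = "oblimin", estimator = "minres")
  expect_true(all(tucker_congruence(ef$loadings, ef3$loadings) > 0.99))
  expect_error(efa(X, 8), "n_factors")
})

test_that("one-factor EFA fit is good when the model is true", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(300 + s)
    lam <- rep(0.7, 6)
    FS <- rnorm(400)
    X <- outer(FS, lam) +
      matrix(rnorm(400 * 6), 400, 6) %*% diag(sqrt(1 - lam^2))
    ef <- efa(X, 1, rotation = "none", estimator = "ml")
    if (is.finite(ef$fit$RMSEA) && ef$fit$RMSEA < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("factor scores from the regression method predict the true factors", {
  set.seed(61)
  L <- cbind(c(rep(0.8, 4), rep(0, 4)), c(rep(0, 4), rep(0.8, 4)))
  FS <- matrix(rnorm(800 * 2), 800, 2)
  X <- FS %*% t(L) +
    matrix(rnorm(800 * 8), 800, 8) %*% diag(sqrt(1 - rowSums(L^2)))
  ef <- efa(X, 2, rotation = "oblimin", estimator = "ml")
  cors <- abs(cor(ef$scores, FS))
  expect_gt(max(cors[1, ]), 0.85)
  expect_gt(max(cors[2, ]), 0.85)
})

test_that("standardized regression equals the normal-equations solution", {
  set.seed(71)
  for (r in 1:100) {
    n <- 40; p <- 3
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(n)
    res <- standardized_regression(y, X)
    zy <- (y - mean(y)) / sd(y)
    zX <- scale(X)
    b_o <- solve(crossprod(zX), crossprod(zX, zy))
    expect_equal(unname(res$beta), as.numeric(b_o), tolerance = 1e-10)
    yhat <- zX %*% b_o
    expect_equal(res$r_squared,
                 1 - sum((zy - yhat)^2) / sum(zy^2) , tolerance = 1e-6)
  }
  # single predictor: beta equals the Pearson correlation
  x1 <- rnorm(50); y1 <- 0.5 * x1 + rnorm(50)
  r1 <- standardized_regression(y1, matrix(x1, dimnames = list(NULL, "x")))
  expect_equal(unname(r1$beta), cor(y1, x1), tolerance = 1e-12)
  # exactly uncorrelated standardized predictors: beta_j = r(y, x_j)
  Z <- scale(matrix(rnorm(50 * 3), 50, 3))
  P <- scale(Z %*% eigen(cov(Z))$vectors)   # principal components: r = 0
  colnames(P) <- c("q1", "q2", "q3")
  y2 <- rnorm(50)
  r2 <- standardized_regression(y2, P)
  for (j in 1:3)
    expect_equal(unname(r2$beta[j]), cor(y2, P[, j]), tolerance = 1e-10)
  # exact collinearity errors with the column named
  Xc <- cbind(a = x1, b = 2 * x1)
  expect_error(standardized_regression(y1, Xc), "collinearity")
})
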