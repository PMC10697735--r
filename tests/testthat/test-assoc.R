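test_that("residualization centers, projects, and matches least squares", {
  set.seed(20)
  X <- matrix(rnorm(200 * 3), 200, 3)
  # no covariates: centering only
  expect_equal(residualize(X), sweep(X, 2, colMeans(X)))
  Z <- matrix(rnorm(200 * 2), 200, 2)
  R <- residualize(X, Z)
  # residuals are mean zero and orthogonal to covariates
  expect_lt(max(abs(colMeans(R))), 1e-12)
  expect_lt(max(abs(crossprod(Z, R))), 1e-9)
  # matches an independent normal-equations solve
  D <- cbind(1, Z)
  R_oracle <- X - D %*% solve(crossprod(D), crossprod(D, X))
  expect_equal(R, R_oracle, ignore_attr = TRUE)
  # idempotence: an already-orthogonal column passes through
  expect_equal(residualize(R, Z), R, tolerance = 1e-10, ignore_attr = TRUE)
  # collinear design is an error
  expect_error(residualize(X, cbind(Z, Z[, 1])), "singular")
})

test_that("the score statistic is sqrt(n) times the Pearson correlation", {
  x <- c(0, 1, 2, 1)
  expect_equal(score_test(x, x), 2)                       # sqrt(4) * cor 1
  expect_equal(score_test(x, c(0, 0, 1, 1)), 2 * cor(x, c(0, 0, 1, 1)))
  expect_equal(score_test(x, c(0, 0, 1, 1)), sqrt(2))     # hand evaluation
  y_orth <- c(1, -1, 1, -1) - mean(c(1, -1, 1, -1))
  expect_equal(score_test(x, y_orth), 0)
  expect_error(score_test(rep(1, 4), x), "zero variance")
  expect_error(score_test(x, rep(0, 4)), "zero variance")
})

test_that("sigma estimation is the pairwise Pearson correlation", {
  expect_equal(estimate_sigma(cbind(c(0, 1, 1, 0))), matrix(1, 1, 1),
               ignore_attr = TRUE)
  set.seed(21)
  M <- matrix(rnorm(100 * 3), 100, 3)
  S <- estimate_sigma(M)
  for (j in 1:3) for (k in 1:3)
    expect_equal(S[j, k], cor(M[, j], M[, k]))
  expect_error(estimate_sigma(cbind(M, 0)), "zero variance")
})

test_that("the omnibus statistic is the quadratic form with known cases", {
  r1 <- omnibus(2.0, matrix(1))
  expect_equal(r1$statistic, 4)
  expect_equal(r1$p_value, pchisq(4, 1, lower.tail = FALSE))
  r2 <- omnibus(c(1, 2, 3), diag(3))
  expect_equal(r2$statistic, 14)  # identity sigma: sum of squares
  expect_equal(r2$df, 3L)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(omnibus(c(1, 1), S)$statistic, 4 / 3)
  # invariance to cluster ordering
  set.seed(22)
  T_scores <- rnorm(4)
  S4 <- cov2cor(crossprod(matrix(rnorm(40), 10, 4)))
  p <- sample(4)
  expect_equal(omnibus(T_scores, S4)$statistic,
               omnibus(T_scores[p], S4[p, p])$statistic)
  # simultaneous sign flip leaves the statistic unchanged
  f <- c(-1, 1, -1, 1)
  expect_equal(omnibus(T_scores * f, diag(f) %*% S4 %*% diag(f))$statistic,
               omnibus(T_scores, S4)$statistic)
  # non-negativity on random draws
  for (i in 1:10) expect_gte(omnibus(rnorm(4), S4)$statistic, 0)
})

test_that("duplicated score correlations trigger the ridge guard", {
  expect_warning(r <- omnibus(c(1, 1), matrix(1, 2, 2)), "ridge")
  expect_true(is.finite(r$statistic))
})

test_that("a single-cluster pipeline reduces to the squared score test", {
  # identical phenotype columns merge into one cluster
  set.seed(23)
  y <- integer(2000); y[sample(2000, 30)] <- 1L
  Y <- cbind(y, y, y)
  g <- simulate_genotypes(2000, 0.3, seed = 24)
  res <- mln_o_test(g, Y)
  expect_equal(res$df, 1L)
  T1 <- score_test(as.numeric(g), y)
  expect_equal(res$statistic, T1^2)
  expect_equal(res$p_value, pchisq(T1^2, 1, lower.tail = FALSE))
})

test_that("duplicated phenotype pairs collapse to the de-duplicated analysis", {
  set.seed(25)
  y1 <- integer(3000); y1[sample(3000, 40)] <- 1L
  y2 <- integer(3000); y2[sample(3000, 40)] <- 1L
  g <- simulate_genotypes(3000, 0.3, seed = 26)
  res_dup <- mln_o_test(g, cbind(y1, y1, y2, y2))
  res_dedup <- mln_o_test(g, cbind(y1, y2))
  expect_equal(res_dup$statistic, res_dedup$statistic)
  expect_equal(res_dup$p_value, res_dedup$p_value)
})

test_that("the harness fast path agrees with the public pipeline", {
  spec <- build_effect_spec(1, K = 30, beta = 0)
  for (seed in 1:3) {
    dat <- simulate_study(spec, n = 5000, maf = 0.3, r = 0.01, seed = seed)
    pub <- mln_o_test(dat$genotypes, dat$phenotypes)
    x <- as.numeric(dat$genotypes)
    cases <- mlno:::.top_m_index(matrix(as.double(dat$phenotypes), 5000), 50L)
    fast <- mlno:::.mlno_from_summary(mlno:::.summary_from_cases(x, cases, 5000L))
    expect_equal(fast$statistic, pub$statistic)
    expect_equal(fast$p_value, pub$p_value)
    expect_equal(fast$assignment$labels, pub$assignment$labels)
  }
})

test_that("covariate adjustment residualizes both sides consistently", {
  set.seed(27)
  n <- 3000
  Z <- cbind(age = rnorm(n), pc1 = rnorm(n))
  spec <- build_effect_spec(1, K = 10, beta = 0)
  dat <- simulate_study(spec, n = n, maf = 0.3, r = 0.02, seed = 28)
  res <- mln_o_test(dat$genotypes, dat$phenotypes, covars = Z)
  expect_true(is.finite(res$statistic))
  expect_gte(res$statistic, 0)
  # projection consistency: score test after residualization equals the
  # score test of pre-orthogonalized vectors
  x_r <- drop(residualize(as.numeric(dat$genotypes), Z))
  y <- merge_phenotypes(dat$phenotypes, res$assignment)[, 1]
  y_r <- drop(residualize(y, Z))
  expect_equal(score_test(x_r, y_r), score_test(drop(residualize(x_r, Z)), y_r),
               tolerance = 1e-10)
  # covariates orthogonal to everything change nothing materially
  res0 <- mln_o_test(dat$genotypes, dat$phenotypes)
  expect_equal(res$df, res0$df)
})

test_that("zero-case phenotypes are dropped and reported by the pipeline", {
  set.seed(29)
  Y <- random_binary_phenos(1000, 5, r = 0.02, seed = 30)
  Y <- cbind(Y, 0L)
  g <- simulate_genotypes(1000, 0.3, seed = 31)
  expect_warning(res <- mln_o_test(g, Y), "zero cases")
  expect_equal(sum(res$kept_phenotypes), 5)
})
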