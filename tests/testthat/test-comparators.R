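test_that("Wilks' lambda matches a direct linear-algebra oracle", {
  # worked 6-observation, K = 2 example: Lambda = det(E) / det(E + H)
  x <- c(0, 1, 2, 0, 1, 2)
  Y <- cbind(c(0.1, 1.2, 2.3, -0.2, 0.8, 1.9),
             c(1.0, 0.4, -0.3, 0.9, 0.2, -0.1))
  fit <- lm(Y ~ x)
  E <- crossprod(resid(fit))
  H <- crossprod(Y - matrix(colMeans(Y), 6, 2, byrow = TRUE)) - E
  lambda_oracle <- det(E) / det(E + H)
  res <- manova_test(x, Y)
  expect_equal(res$wilks, lambda_oracle, tolerance = 1e-10)
  expect_equal(res$statistic, -(6 - 1 - (2 + 2) / 2) * log(lambda_oracle))
  expect_equal(res$df, 2)
})

test_that("single-phenotype Wilks' lambda reduces to 1 - r^2", {
  set.seed(32)
  x <- rnorm(500)
  y <- 0.2 * x + rnorm(500)
  res <- manova_test(x, cbind(y))
  expect_equal(res$wilks, 1 - cor(x, y)^2, tolerance = 1e-10)
})

test_that("MANOVA agrees between the sparse binary path and the dense path", {
  set.seed(33)
  Y <- random_binary_phenos(2000, 8, r = 0.02, seed = 34)
  g <- simulate_genotypes(2000, 0.3, seed = 35)
  res_sparse <- manova_test(g, Y)
  Yd <- Y + 0.0; Yd[1, 1] <- 1e-30  # force the dense fallback
  res_dense <- manova_test(g, Yd)
  expect_equal(res_sparse$statistic, res_dense$statistic, tolerance = 1e-6)
})

test_that("USAT endpoints reduce to its MANOVA and SSU components", {
  set.seed(36)
  Y <- random_binary_phenos(2000, 6, r = 0.02, seed = 37)
  g <- simulate_genotypes(2000, 0.3, seed = 38)
  s <- mlno:::.xy_summary(as.numeric(g), Y)
  only_manova <- usat_test(g, Y, w_grid = 1)
  T_m <- only_manova$T_manova
  expect_equal(only_manova$p_value, pchisq(T_m, 6, lower.tail = FALSE),
               tolerance = 1e-6)
  only_ssu <- usat_test(g, Y, w_grid = 0)
  d <- eigen(s$V, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(only_ssu$p_value,
               mlno:::.wchisq_surv(only_ssu$T_ssu, pmax(d, 0)),
               tolerance = 1e-6)
  # full grid: calibrated p is no smaller than the minimum raw p and valid
  full <- usat_test(g, Y)
  expect_gte(full$p_value, full$statistic)
  expect_lte(full$p_value, 1)
})

test_that("the p-value correlation mapping matches brute-force simulation", {
  set.seed(39)
  n <- 200000
  for (r in c(0, 0.6, 0.95)) {
    z1 <- rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    emp <- cor(2 * pnorm(-abs(z1)), 2 * pnorm(-abs(z2)))
    expect_equal(mlno:::.pvalue_cor(r), emp, tolerance = 0.02)
  }
  expect_equal(mlno:::.pvalue_cor(1), 1, tolerance = 1e-6)
  # negative z correlation maps like its magnitude (two-sided p-values)
  expect_equal(mlno:::.pvalue_cor(-0.6), mlno:::.pvalue_cor(0.6))
})

test_that("TATES reduces to Simes for independent and to min-p for identical phenotypes", {
  set.seed(40)
  # disjoint case sets: essentially uncorrelated phenotypes
  n <- 4000
  Y <- matrix(0L, n, 4)
  for (k in 1:4) Y[((k - 1) * 40 + 1):(k * 40), k] <- 1L
  g <- simulate_genotypes(n, 0.3, seed = 41)
  res <- tates_test(g, Y)
  expect_equal(res$Ke, 4, tolerance = 0.05)
  p <- res$p_univariate
  simes <- min(4 * sort(p) / seq_len(4))
  expect_equal(res$p_value, simes, tolerance = 0.05 * simes + 1e-6)
  # identical columns: effective number 1, p = min p
  y <- integer(n); y[sample(n, 50)] <- 1L
  res1 <- tates_test(g, cbind(y, y, y))
  expect_equal(res1$Ke, 1, tolerance = 1e-6)
  expect_equal(res1$p_value, min(res1$p_univariate), tolerance = 1e-8)
})

test_that("the effective number formula matches a hand eigen computation", {
  R3 <- matrix(c(1, 0.5, 0.2,
                 0.5, 1, 0.4,
                 0.2, 0.4, 1), 3, 3)
  lam <- eigen(R3, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(mlno:::.effective_number(R3),
               3 - sum(pmax(lam - 1, 0)))
})

test_that("the proportional-odds fitter matches MASS::polr", {
  skip_if_not_installed("MASS")
  set.seed(42)
  n <- 400
  Y <- matrix(rbinom(n * 3, 1, 0.15), n, 3)
  eta <- Y %*% c(0.8, -0.5, 0.3)
  # genotype generated to depend on the phenotypes through an ordinal model
  u <- plogis(eta + rnorm(n))
  x <- as.integer(cut(u, c(-Inf, 0.45, 0.8, Inf))) - 1L
  fit <- mlno:::.polr_fit(x, Y)
  expect_true(fit$converged)
  mass_fit <- MASS::polr(factor(x) ~ Y, method = "logistic")
  expect_equal(fit$loglik, as.numeric(logLik(mass_fit)), tolerance = 1e-5)
  expect_equal(sort(fit$beta), sort(unname(coef(mass_fit))), tolerance = 1e-3)
  res <- multiphen_test(x, Y)
  null_ll <- as.numeric(logLik(MASS::polr(factor(x) ~ 1, method = "logistic")))
  expect_equal(res$statistic,
               2 * (as.numeric(logLik(mass_fit)) - null_ll), tolerance = 1e-4)
  expect_equal(res$df, 3)
})

test_that("two observed genotype categories degrade to binary logistic regression", {
  set.seed(43)
  n <- 500
  Y <- matrix(rbinom(n * 2, 1, 0.2), n, 2)
  x <- rbinom(n, 1, plogis(-1 + Y %*% c(0.5, -0.5)))
  res <- multiphen_test(x, Y)
  expect_true(is.finite(res$statistic))
  glm_fit <- glm(x ~ Y, family = binomial())
  glm_null <- glm(x ~ 1, family = binomial())
  lrt <- as.numeric(2 * (logLik(glm_fit) - logLik(glm_null)))
  expect_equal(res$statistic, lrt, tolerance = 1e-5)
})

test_that("the MultiPhen LRT has mean about K under the null", {
  set.seed(44)
  stats <- replicate(60, {
    Y <- matrix(rbinom(1500 * 4, 1, 0.05), 1500, 4)
    x <- simulate_genotypes(1500, 0.3)
    multiphen_test(x, Y)$statistic
  })
  # chi-square_4: mean 4, sd sqrt(8); MC SE of the mean = sqrt(8/60)
  expect_lt(abs(mean(stats) - 4), 3 * sqrt(8 / 60))
})

test_that("all comparators are permutation-equivariant in phenotype order", {
  set.seed(45)
  Y <- random_binary_phenos(2000, 6, r = 0.02, seed = 46)
  g <- simulate_genotypes(2000, 0.3, seed = 47)
  perm <- sample(6)
  expect_equal(manova_test(g, Y)$p_value, manova_test(g, Y[, perm])$p_value)
  expect_equal(usat_test(g, Y)$p_value, usat_test(g, Y[, perm])$p_value,
               tolerance = 1e-10)
  expect_equal(tates_test(g, Y)$p_value, tates_test(g, Y[, perm])$p_value,
               tolerance = 1e-10)
  expect_equal(multiphen_test(g, Y)$p_value,
               multiphen_test(g, Y[, perm])$p_value, tolerance = 1e-6)
  for (f in list(manova_test, usat_test, tates_test, multiphen_test)) {
    p <- f(g, Y)$p_value
    expect_gte(p, 0); expect_lte(p, 1)
  }
})
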