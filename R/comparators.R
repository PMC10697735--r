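# Shared sufficient statistics for the single-SNP multi-phenotype tests.
#
# For binary 0/1 phenotype matrices all centered cross-products are functions
# of the co-occurrence counts A = t(Y) Y, the per-phenotype case counts and
# the genotype sums over case rows, so everything is computed on the
# (typically tiny) submatrix of individuals with at least one case. Dense
# numeric input falls back to ordinary centered cross-products.
.xy_summary <- function(x, Y) {
  x <- as.numeric(x)
  Y <- as.matrix(Y)
  n <- length(x)
  if (nrow(Y) != n) stop("genotype length does not match phenotype rows")
  K <- ncol(Y)
  xbar <- mean(x)
  Sxx <- sum((x - xbar)^2)
  if (Sxx == 0) stop("degenerate input: genotype has zero variance")
  binary <- .is_binary(Y)
  A <- NULL; mj <- NULL
  if (binary) {
    u <- which(rowSums(Y) > 0)
    Ysub <- Y[u, , drop = FALSE]
    storage.mode(Ysub) <- "double"
    A <- crossprod(Ysub)
    mj <- diag(A)
    if (any(mj == 0) || any(mj == n))
      stop("degenerate input: phenotype column(s) with zero variance")
    Syy <- mj - mj^2 / n
    Sxy <- drop(crossprod(Ysub, x[u])) - mj * xbar
    Syy_mat <- A - tcrossprod(mj) / n
  } else {
    Yc <- sweep(Y, 2L, colMeans(Y))
    Syy_mat <- crossprod(Yc)
    Syy <- diag(Syy_mat)
    if (any(Syy == 0))
      stop("degenerate input: phenotype column(s) with zero variance")
    Sxy <- drop(crossprod(Yc, x - xbar))
    u <- seq_len(n); Ysub <- Y
  }
  V <- Syy_mat / sqrt(tcrossprod(Syy))
  list(n = n, K = K, x = x, xbar = xbar, Sxx = Sxx, Sxy = Sxy,
       Syy = Syy, Syy_mat = Syy_mat, V = V,
       z = sqrt(n) * Sxy / sqrt(Sxx * Syy),
       u = u, Ysub = Ysub, A = A, mj = mj, binary = binary)
}

.is_binary <- function(Y) {
  if (is.integer(Y)) {
    r <- range(Y)
    r[1] >= 0L && r[2] <= 1L
  } else {
    all(Y == 0 | Y == 1)
  }
}

.comparator_result <- function(method, statistic, df, p_value, ...) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, ...),
            class = "comparator_result")
}

#' @export
print.comparator_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n", x$method,
              x$statistic, if (is.null(x$df)) "NA" else format(x$df),
              x$p_value))
  invisible(x)
}

# ---- MANOVA -----------------------------------------------------------------

.manova_from_summary <- function(s) {
  R2 <- drop(crossprod(s$Sxy, solve(s$Syy_mat, s$Sxy))) / s$Sxx
  Lambda <- 1 - R2
  if (Lambda <= 0) {
    warning("singular within-group covariance; ridge-guarding Wilks' lambda")
    Syy_mat <- s$Syy_mat + diag(1e-8 * mean(diag(s$Syy_mat)), s$K)
    R2 <- drop(crossprod(s$Sxy, solve(Syy_mat, s$Sxy))) / s$Sxx
    Lambda <- max(1 - R2, .Machine$double.eps)
  }
  stat <- -(s$n - 1 - (s$K + 2) / 2) * log(Lambda)
  list(statistic = stat, lambda = Lambda,
       p_value = pchisq(stat, df = s$K, lower.tail = FALSE))
}

#' MANOVA (Wilks' lambda) association test
#'
#' One-predictor multivariate regression of all phenotypes on the genotype.
#' Wilks' lambda is referred to a chi-square distribution with K degrees of
#' freedom through the Bartlett transformation
#' `-(n - 1 - (K + 2)/2) log(Lambda)`.
#'
#' @param genotype Length-n genotype vector.
#' @param phenos n x K phenotype matrix (binary or numeric).
#' @return `comparator_result` with the Bartlett statistic, `df = K`, the
#'   p-value, and `wilks` (the lambda itself).
#' @export
manova_test <- function(genotype, phenos) {
  s <- .xy_summary(genotype, phenos)
  m <- .manova_from_summary(s)
  .comparator_result("MANOVA", m$statistic, s$K, m$p_value, wilks = m$lambda)
}

# ---- USAT -------------------------------------------------------------------

# Hall-Buckley-Eagleson style three-moment approximation to a positively
# weighted sum of independent 1-df chi-squares: shifted, scaled chi-square.
.wchisq_surv <- function(q, lam) {
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3)
  a <- c3 / c2; nu <- c2^3 / c3^2; b <- c1 - c2^2 / c3
  pchisq((q - b) / a, df = nu, lower.tail = FALSE)
}
.wchisq_quantile <- function(p_upper, lam) {
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3)
  a <- c3 / c2; nu <- c2^3 / c3^2; b <- c1 - c2^2 / c3
  a * qchisq(p_upper, df = nu, lower.tail = FALSE) + b
}

.usat_from_summary <- function(s, w_grid = seq(0, 1, by = 0.1)) {
  d <- eigen(s$V, symmetric = TRUE, only.values = TRUE)$values
  d <- pmax(d, 0)
  T_m <- s$n * drop(crossprod(s$Sxy, solve(s$Syy_mat, s$Sxy))) / s$Sxx
  T_s <- sum(s$z^2)
  p_w <- vapply(w_grid, function(w) {
    .wchisq_surv(w * T_m + (1 - w) * T_s, w + (1 - w) * d)
  }, numeric(1))
  p_min <- min(p_w)
  q_w <- vapply(w_grid, function(w) {
    .wchisq_quantile(p_min, w + (1 - w) * d)
  }, numeric(1))
  sub1 <- w_grid < 1
  m_upper <- if (any(w_grid == 1)) q_w[w_grid == 1][1] else
    qchisq(1e-14, df = s$K, lower.tail = FALSE)
  integrand <- function(m) {
    bound <- vapply(m, function(mm) {
      if (!any(sub1)) return(Inf)
      min((q_w[sub1] - w_grid[sub1] * mm) / (1 - w_grid[sub1]))
    }, numeric(1))
    Fs <- ifelse(is.finite(bound), 1 - .wchisq_surv(bound, d), 1)
    dchisq(m, df = s$K) * Fs
  }
  acc <- integrate(integrand, 0, m_upper, rel.tol = 1e-8,
                   subdivisions = 500L, stop.on.error = FALSE)
  p <- min(max(1 - acc$value, p_min), 1)
  list(statistic = p_min, p_value = p, p_w = p_w,
       T_manova = T_m, T_ssu = T_s)
}

#' USAT: unified score-based association test
#'
#' Combines the MANOVA-type score statistic `T_M = z' V^{-1} z` (chi-square
#' with K df) with the sum-of-squared-scores statistic `T_SSU = z'z`
#' (a weighted chi-square sum) over a grid of weights
#' `T_w = w T_M + (1 - w) T_SSU`, takes the minimum per-weight p-value as
#' the test statistic, and calibrates it by one-dimensional numerical
#' integration over the chi-square density of `T_M`. Per-weight p-values
#' use a three-moment shifted-scaled chi-square approximation; the final
#' integration treats `T_M` and `T_SSU` as independent (see the methods
#' vignette for the approximation level).
#'
#' @inheritParams manova_test
#' @param w_grid Weight grid in \[0, 1\]; default `seq(0, 1, 0.1)`.
#' @return `comparator_result`; `statistic` is the minimum p-value over the
#'   grid, `p_value` its calibrated p-value.
#' @export
usat_test <- function(genotype, phenos, w_grid = seq(0, 1, by = 0.1)) {
  s <- .xy_summary(genotype, phenos)
  r <- .usat_from_summary(s, w_grid)
  .comparator_result("USAT", r$statistic, NA_integer_, r$p_value,
                     p_w = r$p_w, T_manova = r$T_manova, T_ssu = r$T_ssu)
}

# ---- TATES ------------------------------------------------------------------

# Correlation between two-sided p-values of bivariate-normal z-scores as a
# function of the z correlation, computed once by quadrature and cached.
# cor(p1, p2) = 12 (E[p1 p2] - 1/4) since p is Uniform(0,1) marginally.
.mlno_cache <- new.env(parent = emptyenv())
.pvalue_cor_map <- function() {
  if (!is.null(.mlno_cache$pcor)) return(.mlno_cache$pcor)
  zg <- seq(-8, 8, length.out = 321L)
  h <- zg[2] - zg[1]
  wts <- rep(h, length(zg)); wts[c(1, length(zg))] <- h / 2
  phi_w <- wts * dnorm(zg)
  g1 <- 2 * pnorm(-abs(zg))
  rg <- seq(0, 1, by = 0.02)
  pc <- vapply(rg, function(r) {
    s <- sqrt(max(1 - r^2, 0))
    G2 <- 2 * pnorm(-abs(outer(r * zg, s * zg, "+")))
    e <- drop(crossprod(phi_w * g1, G2 %*% phi_w))
    12 * (e - 0.25)
  }, numeric(1))
  pc[rg == 0] <- 0
  pc[rg == 1] <- 1
  .mlno_cache$pcor <- list(r = rg, pcor = pc)
  .mlno_cache$pcor
}

.pvalue_cor <- function(r) {
  map <- .pvalue_cor_map()
  out <- stats::approx(map$r, map$pcor, xout = pmin(abs(r), 1))$y
  out
}

# GATES/TATES effective number of tests from eigenvalues of a correlation
# matrix: Ke = M - sum_{lambda > 1} (lambda - 1).
.effective_number <- function(R) {
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  nrow(R) - sum(pmax(lam - 1, 0))
}

.tates_from_summary <- function(s) {
  p <- 2 * pnorm(-abs(s$z))
  K <- s$K
  Rp <- matrix(.pvalue_cor(s$V), K, K)
  diag(Rp) <- 1
  ord <- order(p)
  p_sorted <- p[ord]
  Rp_sorted <- Rp[ord, ord, drop = FALSE]
  Ke <- .effective_number(Rp_sorted)
  Ke_i <- vapply(seq_len(K), function(i)
    .effective_number(Rp_sorted[seq_len(i), seq_len(i), drop = FALSE]),
    numeric(1))
  p_tates <- min(Ke * p_sorted / Ke_i)
  list(p_value = min(p_tates, 1), p_univariate = p, Ke = Ke)
}

#' TATES: trait-based association test using the extended Simes procedure
#'
#' Computes per-phenotype score-test p-values, estimates the correlation
#' among p-values from the phenotype correlation matrix (by a numerically
#' computed bivariate-normal mapping), converts correlation eigenvalues into
#' effective numbers of tests, and combines the sorted p-values with
#' `p_TATES = min_i Ke * p_(i) / Ke_i`. With uncorrelated phenotypes this
#' is the classical Simes procedure; with perfectly correlated phenotypes
#' it reduces to the minimum p-value.
#'
#' @inheritParams manova_test
#' @return `comparator_result`; `statistic` is the combined p-value itself,
#'   with per-phenotype p-values in `p_univariate` and the effective number
#'   of tests in `Ke`.
#' @export
tates_test <- function(genotype, phenos) {
  Y <- as.matrix(phenos)
  if (ncol(Y) < 2L) {
    s <- .xy_summary(genotype, Y[, 1, drop = FALSE] * 1.0)
    p <- 2 * pnorm(-abs(s$z))
    return(.comparator_result("TATES", p, NA_integer_, p,
                              p_univariate = p, Ke = 1))
  }
  s <- .xy_summary(genotype, Y)
  r <- .tates_from_summary(s)
  .comparator_result("TATES", r$p_value, NA_integer_, r$p_value,
                     p_univariate = r$p_univariate, Ke = r$Ke)
}

# ---- MultiPhen --------------------------------------------------------------

# Proportional-odds (cumulative logit) regression of the genotype category
# on the phenotype matrix, by Newton-Raphson with the observed Hessian.
# Rows whose predictors are all zero share a zero linear predictor, so they
# enter the likelihood only through per-category counts: with extremely
# unbalanced binary phenotypes this collapses almost the whole cohort into
# C pseudo-observations and each iteration costs O(#case rows).
.polr_fit <- function(x, Y, maxit = 100L, tol = 1e-8) {
  Y <- as.matrix(Y)
  nz <- which(rowSums(Y != 0) > 0)
  .polr_core(x, Y[nz, , drop = FALSE], nz, maxit = maxit, tol = tol)
}

# x: full genotype vector; Ynz: predictor rows for the individuals in nz
# (all other rows are all-zero and are collapsed into category counts).
.polr_core <- function(x, Ynz, nz, maxit = 100L, tol = 1e-8) {
  Ynz <- as.matrix(Ynz)
  storage.mode(Ynz) <- "double"
  n <- length(x)
  cats <- sort(unique(x))
  C <- length(cats)
  if (C < 2L) stop("genotype has fewer than 2 observed categories")
  cc_all <- match(x, cats)
  ntab <- tabulate(cc_all, C)
  ll0 <- sum(ntab * log(ntab / n))
  Xc <- rbind(Ynz, matrix(0, C, ncol(Ynz)))
  cc <- c(cc_all[nz], seq_len(C))
  wt <- c(rep(1, length(nz)), ntab - tabulate(cc_all[nz], C))
  K <- ncol(Ynz)
  zeta <- qlogis(cumsum(ntab / n))[seq_len(C - 1L)]
  beta <- numeric(K)
  upper_j <- ifelse(cc <= C - 1L, cc, NA_integer_)
  lower_j <- ifelse(cc >= 2L, cc - 1L, NA_integer_)
  loglik <- function(zeta, beta) {
    eta <- drop(Xc %*% beta)
    uu <- ifelse(is.na(upper_j), Inf, zeta[ifelse(is.na(upper_j), 1L, upper_j)] - eta)
    vv <- ifelse(is.na(lower_j), -Inf, zeta[ifelse(is.na(lower_j), 1L, lower_j)] - eta)
    P <- plogis(uu) - plogis(vv)
    if (any(P <= 0)) return(list(ll = -Inf))
    list(ll = sum(wt * log(P)), uu = uu, vv = vv, P = P)
  }
  st <- loglik(zeta, beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    uu <- st$uu; vv <- st$vv; P <- st$P
    fu <- dlogis(uu); fv <- dlogis(vv)
    Fu <- plogis(uu); Fv <- plogis(vv)
    A <- fu / P; B <- fv / P
    fpu <- fu * (1 - 2 * Fu); fpv <- fv * (1 - 2 * Fv)
    luu <- fpu / P - A^2
    lvv <- -fpv / P - B^2
    luv <- A * B
    # gradient
    gz <- numeric(C - 1L)
    for (j in seq_len(C - 1L)) {
      gz[j] <- sum(wt * A * (!is.na(upper_j) & upper_j == j)) -
               sum(wt * B * (!is.na(lower_j) & lower_j == j))
    }
    gb <- -drop(crossprod(Xc, wt * (A - B)))
    g <- c(gz, gb)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    # Hessian
    H <- matrix(0, C - 1L + K, C - 1L + K)
    for (j in seq_len(C - 1L)) {
      up_j <- !is.na(upper_j) & upper_j == j
      lo_j <- !is.na(lower_j) & lower_j == j
      H[j, j] <- sum(wt * (luu * up_j + lvv * lo_j))
      if (j < C - 1L) {
        # zeta_j as lower cut and zeta_{j+1} as upper cut share category j+1
        both <- !is.na(upper_j) & upper_j == j + 1L & lo_j
        H[j, j + 1L] <- H[j + 1L, j] <- sum(wt * luv * both)
      }
      wzb <- -(wt * ((luu + luv) * up_j + (lvv + luv) * lo_j))
      H[j, C - 1L + seq_len(K)] <- H[C - 1L + seq_len(K), j] <-
        drop(crossprod(Xc, wzb))
    }
    wbb <- wt * (luu + 2 * luv + lvv)
    H[C - 1L + seq_len(K), C - 1L + seq_len(K)] <- crossprod(Xc * wbb, Xc)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    fac <- 1
    repeat {
      zeta_new <- zeta - fac * step[seq_len(C - 1L)]
      beta_new <- beta - fac * step[C - 1L + seq_len(K)]
      if (!is.unsorted(zeta_new)) {
        st_new <- loglik(zeta_new, beta_new)
        if (is.finite(st_new$ll) && st_new$ll >= st$ll - 1e-12) break
      }
      fac <- fac / 2
      if (fac < 1e-8) { st_new <- st; zeta_new <- zeta; beta_new <- beta; break }
    }
    if (fac < 1e-8) break
    zeta <- zeta_new; beta <- beta_new; st <- st_new
  }
  list(loglik = st$ll, loglik_null = ll0, zeta = zeta, beta = beta,
       converged = converged, iterations = it, n_categories = C)
}

#' MultiPhen: ordinal regression of genotype on phenotypes
#'
#' Proportional-odds logistic regression of the genotype category (0/1/2
#' minor-allele count) on all phenotypes jointly, tested against the
#' intercept-only model by a likelihood ratio test with K degrees of
#' freedom. Genotypes with only two observed categories degrade to binary
#' logistic regression. Non-convergence is flagged in the result, not an
#' error.
#'
#' @inheritParams manova_test
#' @return `comparator_result` with the LRT `statistic`, `df = K`,
#'   `p_value`, and a `converged` flag.
#' @export
multiphen_test <- function(genotype, phenos) {
  Y <- as.matrix(phenos)
  fit <- .polr_fit(as.numeric(genotype), Y)
  lrt <- 2 * (fit$loglik - fit$loglik_null)
  .comparator_result("MultiPhen", lrt, ncol(Y),
                     pchisq(lrt, df = ncol(Y), lower.tail = FALSE),
                     converged = fit$converged,
                     iterations = fit$iterations)
}
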