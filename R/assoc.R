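#' Residualize columns on covariates
#'
#' Replaces every column of `target` by its least-squares residual against
#' an intercept plus the covariate columns. With `covars = NULL` this is
#' plain centering. Residual columns are mean-zero and orthogonal to every
#' covariate.
#'
#' @param target n x m numeric matrix (or vector) to adjust.
#' @param covars Optional n x p numeric covariate matrix (no intercept
#'   column; one is added internally).
#' @return Matrix of residuals with the shape of `target`.
#' @export
residualize <- function(target, covars = NULL) {
  X <- as.matrix(target)
  if (is.null(covars) || ncol(as.matrix(covars)) == 0L)
    return(sweep(X, 2L, colMeans(X)))
  Z <- cbind(`(Intercept)` = 1, as.matrix(covars))
  if (qr(Z)$rank < ncol(Z))
    stop("singular covariate design: columns are collinear after adding an intercept")
  fit <- lm.fit(Z, X)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(X)
  res
}

#' Score statistic for one merged phenotype against a genotype
#'
#' The score test of the genotype coefficient in the generalized linear
#' model of a (merged) phenotype on the SNP, in the normalisation
#' `T = sqrt(n) * cor(x, y)`, which is asymptotically standard normal under
#' the null. The same form serves binary merged phenotypes (identity-link
#' working model) and continuous residualized phenotypes.
#'
#' @param x Genotype vector (0/1/2 counts, or residualized dosage).
#' @param y Phenotype vector of the same length.
#' @return Scalar score statistic.
#' @examples
#' score_test(c(0, 1, 2, 1), c(0, 0, 1, 1))  # = 2 * cor = sqrt(2)
#' @export
score_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (var(x) == 0) stop("degenerate input: genotype has zero variance")
  if (var(y) == 0) stop("degenerate input: phenotype has zero variance")
  sqrt(n) * cor(x, y)
}

#' Correlation matrix of merged phenotypes
#'
#' Pearson correlation matrix of the L merged phenotype columns, used as
#' the estimate of the correlation of the per-cluster score statistics in
#' the omnibus combination.
#'
#' @param merged n x L matrix of merged (possibly residualized) phenotypes.
#' @return L x L symmetric correlation matrix with unit diagonal.
#' @export
estimate_sigma <- function(merged) {
  M <- as.matrix(merged)
  v <- apply(M, 2L, var)
  if (any(v == 0))
    stop("degenerate input: merged phenotype column(s) with zero variance: ",
         paste(which(v == 0), collapse = ", "))
  cor(M)
}

#' Omnibus combination of per-cluster score statistics
#'
#' Combines the vector of per-cluster score statistics with the inverse of
#' their estimated correlation matrix into the quadratic form
#' `T_omni = T' Sigma^{-1} T`, which is chi-square with L degrees of
#' freedom under the global null. Near-singular `Sigma` (condition number
#' above 1e8) is ridge-regularised by 1e-8 on the diagonal with a warning.
#'
#' @param T_scores Length-L numeric vector of score statistics.
#' @param sigma L x L correlation matrix from [estimate_sigma()].
#' @return Object of class `mlno_result`: list with `statistic`, `df`,
#'   `p_value`, `sigma` and `cluster_stats`.
#' @export
omnibus <- function(T_scores, sigma) {
  T_scores <- as.numeric(T_scores)
  sigma <- as.matrix(sigma)
  L <- length(T_scores)
  stopifnot(nrow(sigma) == L, ncol(sigma) == L)
  kap <- kappa(sigma, exact = FALSE)
  if (!is.finite(kap) || kap > 1e8) {
    warning(sprintf(
      "near-singular score correlation matrix (condition number %.3g); adding ridge 1e-8", kap))
    sigma <- sigma + diag(1e-8, L)
  }
  stat <- drop(crossprod(T_scores, solve(sigma, T_scores)))
  structure(list(statistic = stat, df = L,
                 p_value = pchisq(stat, df = L, lower.tail = FALSE),
                 sigma = sigma, cluster_stats = T_scores),
            class = "mlno_result")
}

#' @export
print.mlno_result <- function(x, ...) {
  cat("MLN-O omnibus association test\n")
  cat(sprintf("  clusters (df): %d\n", x$df))
  cat(sprintf("  statistic:     %.4f\n", x$statistic))
  cat(sprintf("  p-value:       %.4g\n", x$p_value))
  if (!is.null(x$assignment))
    cat(sprintf("  modularity Q:  %.4f\n", x$assignment$Q))
  invisible(x)
}

#' MLN-O: joint association test of a SNP with unbalanced binary phenotypes
#'
#' Runs the full three-step pipeline: build the case co-occurrence network
#' and its normalised similarity ([build_adjacency()], [similarity()]),
#' cluster phenotypes by modularity-scored complete linkage and merge
#' clusters by logical union ([select_clusters()], [merge_phenotypes()]),
#' then compute per-cluster score statistics, estimate their correlation
#' from the merged phenotypes, and combine with the omnibus chi-square
#' statistic ([omnibus()]). With covariates, merged phenotypes and genotype
#' are first replaced by their linear-regression residuals.
#'
#' @param genotype Length-n vector of minor-allele counts (0/1/2).
#' @param phenos n x K binary phenotype matrix; phenotypes with zero cases
#'   are dropped with a warning.
#' @param covars Optional n x p covariate matrix (e.g. principal
#'   components, sex, age); an intercept is handled internally.
#' @return `mlno_result` with the omnibus `statistic`, `df` (number of
#'   clusters used), `p_value`, `sigma`, per-cluster `cluster_stats`, and
#'   the cluster `assignment`.
#' @examples
#' set.seed(1)
#' spec <- build_effect_spec(1, K = 20, beta = 0)
#' dat <- simulate_study(spec, n = 4000, maf = 0.3, r = 0.01)
#' mln_o_test(dat$genotypes, dat$phenotypes)
#' @export
mln_o_test <- function(genotype, phenos, covars = NULL) {
  x <- as.numeric(genotype)
  Y <- as.matrix(phenos)
  if (length(x) != nrow(Y))
    stop("[network stage] genotype length does not match phenotype rows")
  A <- build_adjacency(Y)
  kept <- attr(A, "kept")
  if (!all(kept)) Y <- Y[, kept, drop = FALSE]
  W <- similarity(A)
  assignment <- select_clusters(W)
  merged <- merge_phenotypes(Y, assignment)
  if (!is.null(covars)) {
    merged <- residualize(merged, covars)
    x <- drop(residualize(x, covars))
  }
  v <- apply(merged, 2L, var)
  drop_l <- v == 0
  if (any(drop_l)) {
    warning("[score stage] dropping ", sum(drop_l),
            " zero-variance merged cluster(s); degrees of freedom reduced")
    merged <- merged[, !drop_l, drop = FALSE]
  }
  if (ncol(merged) == 0L) stop("[score stage] no testable clusters remain")
  T_scores <- vapply(seq_len(ncol(merged)),
                     function(l) score_test(x, merged[, l]), numeric(1))
  sigma <- estimate_sigma(merged)
  res <- omnibus(T_scores, sigma)
  res$assignment <- assignment
  res$kept_phenotypes <- kept
  res
}
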