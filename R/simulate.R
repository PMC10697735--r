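#' Simulate SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Draws minor-allele counts for `n` unrelated individuals at a biallelic SNP
#' with minor allele frequency `maf`, assuming Hardy-Weinberg equilibrium:
#' P(2) = maf^2, P(1) = 2 maf (1 - maf), P(0) = (1 - maf)^2.
#'
#' @param n Sample size (number of individuals).
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param seed Optional integer seed; when supplied, `set.seed(seed)` is
#'   called first so the draw is reproducible.
#' @return Integer vector of length `n` with values in \{0, 1, 2\} and
#'   attribute `maf`.
#' @examples
#' g <- simulate_genotypes(1000, maf = 0.3, seed = 1)
#' table(g)
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive sample size")
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop("`maf` must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  g <- rbinom(as.integer(n), 2L, maf)
  attr(g, "maf") <- maf
  g
}

#' Effect-size and loading specification for the simulation models
#'
#' Builds the effect vector `lambda` and block-diagonal loading structure
#' `gamma` for one of the five published simulation models. All models place
#' `K` phenotypes into `R` equal blocks (factors); the genotype affects a
#' subset of blocks:
#'
#' * **Model 1** (R = 5): blocks 1-3 null; blocks 4 and 5 all equal `beta`.
#' * **Model 2** (R = 5): block 4 equal `-beta`, block 5 equal `beta`.
#' * **Model 3** (R = 5): block 4 equal `-beta`, block 5 the increasing ramp
#'   `2 beta / (k + 1) * (1, ..., k)` with `k = K/5`.
#' * **Model 4** (R = 10): blocks 1-6 null; blocks 7 and 8 carry the
#'   triangular pattern `(1, ..., k/2, k/2, ..., 1) * beta / (k/2 + 1)`
#'   (negative in block 7, positive in block 8); block 9 equal `-beta`,
#'   block 10 equal `beta`.
#' * **Model 5** (R = 50): factors 1-40 null, factors 41-45 equal `beta`,
#'   factors 46-50 equal `-beta`.
#'
#' @param model_id Integer 1 to 5.
#' @param K Number of phenotypes; must be divisible by the model's factor
#'   count (and by `2R` for Model 4's triangular pattern).
#' @param beta Scalar genotype effect size on the liabilities; `beta = 0`
#'   gives the global null.
#' @param c2 Within-factor phenotype correlation (the squared factor
#'   loading), default 0.4.
#' @param rho_c2 Between-factor phenotype correlation, default 0.24 (so the
#'   factor-factor correlation is `rho = rho_c2 / c2`).
#' @return An object of class `factor_model_spec`: a list with `K`, `R`,
#'   `lambda` (length `K`), `gamma` (K x R 0/1 block-diagonal matrix),
#'   `block` (factor index per phenotype), `c` (loading, `sqrt(c2)`) and
#'   `rho`.
#' @examples
#' spec <- build_effect_spec(1, K = 100, beta = 0.1)
#' table(spec$lambda)
#' @export
build_effect_spec <- function(model_id, K, beta, c2 = 0.4, rho_c2 = 0.24) {
  if (!model_id %in% 1:5) stop("`model_id` must be one of 1..5")
  R <- c(5L, 5L, 5L, 10L, 50L)[model_id]
  if (K %% R != 0)
    stop(sprintf("K = %d is not divisible by the model's factor count R = %d",
                 K, R))
  k <- K %/% R
  if (model_id == 4L && k %% 2 != 0)
    stop("Model 4 requires an even block size K/10 for its triangular pattern")
  if (c2 < 0 || c2 > 1) stop("`c2` must lie in [0, 1]")
  rho <- if (c2 > 0) rho_c2 / c2 else 0
  if (rho <= -1 / (R - 1) || rho > 1)
    stop("factor correlation rho = rho_c2/c2 outside (-1/(R-1), 1]: ",
         "factor covariance not positive definite")
  flat <- function(s) rep(s * beta, k)
  lambda <- switch(model_id,
    c(rep(0, 3 * k), flat(1), flat(1)),
    c(rep(0, 3 * k), flat(-1), flat(1)),
    c(rep(0, 3 * k), flat(-1), 2 * beta / (k + 1) * seq_len(k)),
    {
      tri <- c(seq_len(k / 2), rev(seq_len(k / 2))) * beta / (k / 2 + 1)
      c(rep(0, 6 * k), -tri, tri, flat(-1), flat(1))
    },
    c(rep(0, 40 * k), rep(beta, 5 * k), rep(-beta, 5 * k))
  )
  block <- rep(seq_len(R), each = k)
  gamma <- matrix(0L, K, R)
  gamma[cbind(seq_len(K), block)] <- 1L
  structure(
    list(model_id = model_id, K = as.integer(K), R = R,
         lambda = lambda, gamma = gamma, block = block,
         c = sqrt(c2), rho = rho, beta = beta),
    class = "factor_model_spec")
}

#' @export
print.factor_model_spec <- function(x, ...) {
  cat(sprintf(
    "Factor model %d: K = %d phenotypes in R = %d blocks, beta = %g\n",
    x$model_id, x$K, x$R, x$beta))
  cat(sprintf("  within-factor cor = %.3f, between-factor cor = %.3f\n",
              x$c^2, x$rho * x$c^2))
  invisible(x)
}

#' Simulate quantitative liabilities from a factor model
#'
#' Generates the n x K liability matrix
#' `y = lambda * x + c * gamma f + sqrt(1 - c^2) * eps`, where the factors
#' `f` are multivariate normal with exchangeable covariance
#' `(1 - rho) I + rho J` and `eps` is iid standard normal. Under the null
#' (`beta = 0`) the phenotype correlation is `c^2` within a factor block and
#' `rho c^2` between blocks.
#'
#' @param spec A [build_effect_spec()] object.
#' @param genotypes Genotype vector from [simulate_genotypes()] (length n).
#' @param seed Optional integer seed.
#' @return n x K numeric matrix of liabilities.
#' @export
simulate_quantitative <- function(spec, genotypes, seed = NULL) {
  stopifnot(inherits(spec, "factor_model_spec"))
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(genotypes)
  if (spec$rho >= 0) {
    y <- .liability_rng(x, spec$lambda, spec$block, spec$R, spec$c, spec$rho)
  } else {
    # negative exchangeable correlation: draw factors via the Cholesky root
    S <- (1 - spec$rho) * diag(spec$R) + spec$rho
    f <- matrix(rnorm(length(x) * spec$R), length(x)) %*% chol(S)
    y <- .liability_with_factors(x, spec$lambda, spec$block, f, spec$c)
  }
  y
}

#' Dichotomize liabilities into extremely unbalanced binary phenotypes
#'
#' Applies the liability-threshold rule: per phenotype, the `round(n * r)`
#' individuals with the largest liabilities are cases (1), all others
#' controls (0). Rounding is base R's round-half-to-even; ties at the
#' threshold (probability zero under a continuous model) are broken by
#' smallest row index, so the output is deterministic.
#'
#' @param liab n x K numeric liability matrix.
#' @param r Case-control ratio (proportion of cases), with `round(n*r) >= 1`.
#' @return n x K integer 0/1 matrix with exactly `round(n*r)` ones per
#'   column; attribute `case_control_ratio` records `r`.
#' @examples
#' liab <- matrix(c(3, 1, 2, 0, 5, 4), 3)
#' dichotomize(liab, r = 1/3)
#' @export
dichotomize <- function(liab, r) {
  liab <- as.matrix(liab)
  n <- nrow(liab)
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1)
    stop("`r` must be a single ratio in (0, 1)")
  m <- as.integer(round(n * r))
  if (m < 1L)
    stop(sprintf("degenerate case-control ratio: round(n*r) = round(%g) = 0",
                 n * r))
  idx <- .top_m_index(liab, m)
  out <- matrix(0L, n, ncol(liab), dimnames = dimnames(liab))
  out[cbind(as.vector(idx), rep(seq_len(ncol(liab)), each = m))] <- 1L
  attr(out, "case_control_ratio") <- r
  out
}

#' One full phenotype simulation replicate
#'
#' Convenience wrapper: genotypes under HWE, liabilities from the factor
#' model, and dichotomized binary phenotypes.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams dichotomize
#' @param spec A [build_effect_spec()] object.
#' @return List with `genotypes` and `phenotypes` (n x K binary matrix).
#' @export
simulate_study <- function(spec, n, maf = 0.3, r, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_genotypes(n, maf)
  y <- simulate_quantitative(spec, g)
  list(genotypes = g, phenotypes = dichotomize(y, r))
}
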