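.mlno_methods <- c("MLN-O", "MANOVA", "USAT", "TATES", "MultiPhen")

#' Configuration for a Monte-Carlo simulation experiment
#'
#' Bundles and validates the settings of a type-I-error or power study:
#' simulation model, sample size, number of phenotypes, case-control ratio,
#' allele frequency, phenotype correlation structure, effect size(s),
#' replicate count, significance levels, methods and master seed. Defaults
#' follow the published study design: MAF 0.3, within-factor correlation
#' 0.4, between-factor correlation 0.24.
#'
#' @param model_id Simulation model, 1 to 5 (see [build_effect_spec()]).
#' @param n Sample size per replicate.
#' @param K Number of phenotypes.
#' @param r Case-control ratio (0.001 or 0.002 in the published settings).
#' @param maf Minor allele frequency.
#' @param c2,rho_c2 Within- and between-factor phenotype correlations.
#' @param beta Effect size; scalar 0 for type I error, a nonzero scalar or
#'   grid for power.
#' @param replicates Number of Monte-Carlo replicates (>= 1).
#' @param alpha_levels Significance levels in (0, 1).
#' @param methods Subset of `c("MLN-O", "MANOVA", "USAT", "TATES",
#'   "MultiPhen")`.
#' @param seed Master integer seed; per-replicate seeds are derived by a
#'   fixed counter scheme so results do not depend on execution order.
#' @return Validated list of class `experiment_config`.
#' @export
experiment_config <- function(model_id = 1, n = 20000, K = 100, r = 0.001,
                              maf = 0.3, c2 = 0.4, rho_c2 = 0.24, beta = 0,
                              replicates = 1000, alpha_levels = 0.05,
                              methods = "MLN-O", seed = 1) {
  methods <- match.arg(methods, .mlno_methods, several.ok = TRUE)
  if (replicates < 1) stop("`replicates` must be >= 1")
  if (any(alpha_levels <= 0 | alpha_levels >= 1))
    stop("`alpha_levels` must lie in (0, 1)")
  # validate the model structure up front
  invisible(build_effect_spec(model_id, K, beta = max(abs(beta)),
                              c2 = c2, rho_c2 = rho_c2))
  if (round(n * r) < 1) stop("degenerate ratio: round(n*r) < 1")
  structure(list(model_id = model_id, n = as.integer(n), K = as.integer(K),
                 r = r, maf = maf, c2 = c2, rho_c2 = rho_c2, beta = beta,
                 replicates = as.integer(replicates),
                 alpha_levels = alpha_levels, methods = methods,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Per-replicate seed: a documented counter scheme keyed by replicate index,
# so any execution order (or worker partition) reproduces the same draws.
# Kept exact in double arithmetic and below 2^31.
.rep_seed <- function(master, index) {
  ((master %% 2147483647) + index * 2654435761) %% 2147483647
}

# Build the binary-phenotype sufficient summary directly from the m x K
# matrix of case indices (the dichotomizer's internal form), without
# materialising the n x K phenotype matrix.
.summary_from_cases <- function(x, caseidx, n) {
  K <- ncol(caseidx)
  m <- nrow(caseidx)
  u <- sort(unique(as.vector(caseidx)))
  Ysub <- matrix(0, length(u), K)
  Ysub[cbind(match(as.vector(caseidx), u), rep(seq_len(K), each = m))] <- 1
  xbar <- mean(x)
  Sxx <- sum((x - xbar)^2)
  A <- crossprod(Ysub)
  mj <- diag(A)
  Syy <- mj - mj^2 / n
  Sxy <- drop(crossprod(Ysub, x[u])) - mj * xbar
  Syy_mat <- A - tcrossprod(mj) / n
  list(n = n, K = K, x = x, xbar = xbar, Sxx = Sxx, Sxy = Sxy,
       Syy = Syy, Syy_mat = Syy_mat,
       V = Syy_mat / sqrt(tcrossprod(Syy)),
       z = sqrt(n) * Sxy / sqrt(Sxx * Syy),
       u = u, Ysub = Ysub, A = A, mj = mj, binary = TRUE)
}

# Full MLN-O pipeline on a binary sufficient summary: similarity network,
# modularity-selected clustering, merged-phenotype score tests and omnibus
# combination, all through the case-row reduction.
.mlno_from_summary <- function(s) {
  W <- similarity(s$A)
  assignment <- select_clusters(W)
  L <- assignment$L
  M <- vapply(seq_len(L), function(l) {
    as.numeric(rowSums(s$Ysub[, assignment$labels == l, drop = FALSE]) > 0)
  }, numeric(nrow(s$Ysub)))
  nl <- colSums(M)
  Syy_l <- nl - nl^2 / s$n
  sxy <- drop(crossprod(M, s$x[s$u])) - nl * s$xbar
  T_scores <- sqrt(s$n) * sxy / sqrt(s$Sxx * Syy_l)
  sigma <- (crossprod(M) - tcrossprod(nl) / s$n) / sqrt(tcrossprod(Syy_l))
  res <- omnibus(T_scores, sigma)
  res$assignment <- assignment
  res
}

.multiphen_from_summary <- function(s) {
  fit <- .polr_core(s$x, s$Ysub, s$u)
  lrt <- 2 * (fit$loglik - fit$loglik_null)
  list(statistic = lrt,
       p_value = pchisq(lrt, df = s$K, lower.tail = FALSE),
       converged = fit$converged)
}

# One simulated replicate: fresh genotype and phenotypes, then every
# requested test on the shared sufficient summary. Returns p-values (NA on
# failure). Uses the fused generator, which never materialises the n x K
# liability matrix but draws the identical stream as
# simulate_quantitative() + dichotomize().
.replicate_pvalues <- function(spec, n, maf, r, methods) {
  g <- simulate_genotypes(n, maf)
  m <- as.integer(round(n * r))
  x <- as.numeric(g)
  caseidx <- if (spec$rho >= 0) {
    .sim_case_index(x, spec$lambda, spec$block, spec$R, spec$c, spec$rho, m)
  } else {
    .top_m_index(simulate_quantitative(spec, g), m)
  }
  s <- .summary_from_cases(x, caseidx, n)
  vapply(methods, function(mth) {
    tryCatch(switch(mth,
      "MLN-O" = .mlno_from_summary(s)$p_value,
      "MANOVA" = .manova_from_summary(s)$p_value,
      "USAT" = .usat_from_summary(s)$p_value,
      "TATES" = .tates_from_summary(s)$p_value,
      "MultiPhen" = .multiphen_from_summary(s)$p_value),
      error = function(e) NA_real_)
  }, numeric(1))
}

.rate_row <- function(p, alpha, reps) {
  hits <- sum(p < alpha, na.rm = TRUE)
  rate <- hits / reps  # failures count as non-rejections
  data.frame(rate = rate, mc_se = sqrt(rate * (1 - rate) / reps),
             replicates = reps, failures = sum(is.na(p)))
}

#' Type I error study
#'
#' Runs the configured number of null replicates (`beta` forced to 0): per
#' replicate a fresh genotype and phenotype matrix are simulated and every
#' configured method is applied. Returns the empirical rejection fraction
#' at each significance level with its Monte-Carlo standard error
#' `sqrt(rate (1 - rate) / replicates)`. Failed fits are counted as
#' non-rejections and tallied in the `failures` column. Deterministic given
#' `config$seed`: the harness pins the RNG to Mersenne-Twister with the
#' Kinderman-Ramage normal generator for the duration of the run (restoring
#' the caller's settings afterwards) and seeds every replicate from the
#' master seed by a fixed counter scheme.
#'
#' @param config An [experiment_config()].
#' @return Data frame with one row per (method, alpha): columns `method`,
#'   `model`, `n`, `r`, `alpha`, `rate`, `mc_se`, `replicates`, `failures`.
#'   The matrix of per-replicate p-values is in attribute `pvalues`.
#' @export
run_type1 <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  spec <- build_effect_spec(config$model_id, config$K, beta = 0,
                            c2 = config$c2, rho_c2 = config$rho_c2)
  P <- matrix(NA_real_, config$replicates, length(config$methods),
              dimnames = list(NULL, config$methods))
  old_rng <- RNGkind("Mersenne-Twister", normal.kind = "Kinderman-Ramage")
  on.exit(RNGkind(old_rng[1], normal.kind = old_rng[2]), add = TRUE)
  for (i in seq_len(config$replicates)) {
    set.seed(.rep_seed(config$seed, i))
    P[i, ] <- .replicate_pvalues(spec, config$n, config$maf, config$r,
                                 config$methods)
  }
  out <- do.call(rbind, lapply(config$methods, function(mth) {
    do.call(rbind, lapply(config$alpha_levels, function(a) {
      cbind(data.frame(method = mth, model = config$model_id, n = config$n,
                       r = config$r, alpha = a),
            .rate_row(P[, mth], a, config$replicates))
    }))
  }))
  rownames(out) <- NULL
  attr(out, "pvalues") <- P
  out
}

#' Power study
#'
#' Runs the configured replicates at each nonzero effect size in
#' `config$beta` and reports the rejection fraction per method at each
#' significance level, with Monte-Carlo standard errors. The same
#' per-replicate seeds are reused across effect sizes, so power curves are
#' comparable replicate by replicate.
#'
#' @param config An [experiment_config()] with a nonempty `beta` grid.
#' @return Data frame as [run_type1()], with an additional `beta` column.
#' @export
run_power <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  betas <- config$beta
  if (length(betas) < 1) stop("`beta` grid is empty")
  old_rng <- RNGkind("Mersenne-Twister", normal.kind = "Kinderman-Ramage")
  on.exit(RNGkind(old_rng[1], normal.kind = old_rng[2]), add = TRUE)
  out <- do.call(rbind, lapply(betas, function(b) {
    spec <- build_effect_spec(config$model_id, config$K, beta = b,
                              c2 = config$c2, rho_c2 = config$rho_c2)
    P <- matrix(NA_real_, config$replicates, length(config$methods),
                dimnames = list(NULL, config$methods))
    for (i in seq_len(config$replicates)) {
      set.seed(.rep_seed(config$seed, i))
      P[i, ] <- .replicate_pvalues(spec, config$n, config$maf, config$r,
                                   config$methods)
    }
    do.call(rbind, lapply(config$methods, function(mth) {
      do.call(rbind, lapply(config$alpha_levels, function(a) {
        cbind(data.frame(method = mth, model = config$model_id,
                         n = config$n, r = config$r, beta = b, alpha = a),
              .rate_row(P[, mth], a, config$replicates))
      }))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Binomial Monte-Carlo confidence band for a rejection rate
#'
#' The 95% band `alpha +/- 1.96 sqrt(alpha (1 - alpha) / reps)` around a
#' nominal significance level under `reps` Monte-Carlo replicates; an
#' empirical type I error rate inside the band is consistent with nominal
#' calibration.
#'
#' @param alpha Nominal significance level in (0, 1).
#' @param reps Number of replicates (>= 1).
#' @return Numeric vector `c(lower, upper)` (exact values; round for
#'   display).
#' @examples
#' round(confidence_band(0.05, 100000), 5)
#' @export
confidence_band <- function(alpha, reps) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (reps < 1) stop("`reps` must be >= 1")
  half <- 1.96 * sqrt(alpha * (1 - alpha) / reps)
  c(lower = alpha - half, upper = alpha + half)
}
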