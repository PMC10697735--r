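#' Case co-occurrence adjacency matrix of the multi-layer network
#'
#' Each individual defines one network layer: an edge joins phenotypes j and
#' k when the individual is a case for both (including j = k, so the
#' diagonal counts cases per phenotype). Summing the layers over all
#' individuals gives the K x K adjacency matrix `A`, with `A[j, k]` the
#' number of individuals who are cases for both phenotypes. Individuals with
#' no case status contribute nothing, so the sum is taken over individuals
#' with at least one case — provably identical to using the full cohort, and
#' far cheaper when case-control ratios are extreme.
#'
#' @param phenos n x K binary (0/1) phenotype matrix; columns may be named.
#' @param drop_zero_cases Phenotypes with zero cases make the similarity
#'   normalisation degenerate; when `TRUE` (default) they are dropped with a
#'   warning and recorded in the `kept` attribute, when `FALSE` they are an
#'   error.
#' @return K' x K' symmetric integer matrix of co-occurrence counts with
#'   attribute `kept` (logical mask of retained input columns).
#' @examples
#' Y <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(0, 0, 0))
#' build_adjacency(Y)
#' @export
build_adjacency <- function(phenos, drop_zero_cases = TRUE) {
  Y <- as.matrix(phenos)
  if (ncol(Y) < 2L) stop("need at least two phenotypes")
  if (!all(Y == 0L | Y == 1L)) stop("phenotype matrix must be binary 0/1")
  cases <- colSums(Y)
  kept <- cases > 0
  if (!all(kept)) {
    offenders <- colnames(Y)[!kept]
    if (is.null(offenders)) offenders <- which(!kept)
    if (!drop_zero_cases)
      stop("phenotype(s) with zero cases: ", paste(offenders, collapse = ", "))
    warning("dropping ", sum(!kept), " phenotype(s) with zero cases: ",
            paste(offenders, collapse = ", "))
    Y <- Y[, kept, drop = FALSE]
  }
  # restrict to layers that contribute (>= 1 case); A = t(Y) %*% Y
  any_case <- rowSums(Y) > 0
  A <- crossprod(Y[any_case, , drop = FALSE])
  storage.mode(A) <- "integer"
  attr(A, "kept") <- kept
  A
}

#' Normalised similarity matrix of the multi-layer network
#'
#' Transforms the co-occurrence adjacency into
#' `W = diag(A)^{-1/2} A diag(A)^{-1/2}`, i.e.
#' `W[j, k] = A[j, k] / sqrt(A[j, j] * A[k, k])`. Entries lie in \[0, 1\]
#' (Cauchy-Schwarz on co-occurrence counts) with unit diagonal.
#'
#' @param adj Adjacency matrix from [build_adjacency()]; all diagonal
#'   entries must be strictly positive.
#' @return K x K symmetric numeric matrix with unit diagonal.
#' @export
similarity <- function(adj) {
  A <- as.matrix(adj)
  d <- diag(A)
  if (any(d <= 0)) {
    offenders <- colnames(A)[d <= 0]
    if (is.null(offenders)) offenders <- which(d <= 0)
    stop("degenerate phenotype(s) with zero cases on the adjacency diagonal: ",
         paste(offenders, collapse = ", "))
  }
  s <- 1 / sqrt(d)
  W <- A * tcrossprod(s)
  diag(W) <- 1
  W
}
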