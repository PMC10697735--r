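# Partition the leaves of an hclust merge tree into k0 clusters by undoing
# the last k0-1 agglomerations. Identical to cutree() when merge heights
# are distinct, but remains consistent with the agglomeration order when
# heights tie (common here: many phenotype pairs share dissimilarity 1).
.cut_merge_tree <- function(merge, K, k0) {
  n_merge <- K - k0
  par <- integer(K + n_merge)
  if (n_merge > 0) {
    for (t in seq_len(n_merge)) {
      for (ch in merge[t, ]) {
        child <- if (ch < 0) -ch else K + ch
        par[child] <- K + t
      }
    }
  }
  root <- integer(K)
  for (i in seq_len(K)) {
    node <- i
    while (par[node] != 0L) node <- par[node]
    root[i] <- node
  }
  as.integer(factor(root, levels = unique(root)))
}

# Modularity at every cluster count 1..K in one O(K^2) pass: walking the
# agglomeration sequence, merging clusters a and b changes the modularity
# numerator by twice their cross-cluster sum of B = W - d d'/2D.
.modularity_curve <- function(W, hc) {
  K <- ncol(W)
  d <- rowSums(W)
  twoD <- sum(d)
  B <- W - tcrossprod(d) / twoD
  Cs <- matrix(0, 2 * K - 1, 2 * K - 1)
  Cs[seq_len(K), seq_len(K)] <- B
  Q <- numeric(K)
  q <- sum(diag(B))
  Q[K] <- q
  for (t in seq_len(K - 1)) {
    ab <- ifelse(hc$merge[t, ] < 0, -hc$merge[t, ], K + hc$merge[t, ])
    a <- ab[1]; b <- ab[2]
    q <- q + 2 * Cs[a, b]
    new <- K + t
    rn <- Cs[a, ] + Cs[b, ]
    Cs[new, ] <- rn
    Cs[, new] <- rn
    Cs[new, new] <- Cs[a, a] + Cs[b, b] + 2 * Cs[a, b]
    Q[K - t] <- q
  }
  Q / twoD
}

#' Complete-linkage cut of the phenotype similarity matrix
#'
#' Runs complete-linkage agglomerative clustering on the dissimilarity
#' `1 - W` (bounded in \[0, 1\] since `W` is) and cuts the dendrogram into
#' exactly `k0` clusters. Cutting follows the agglomeration order, so tied
#' merge heights are resolved deterministically.
#'
#' @param W Similarity matrix from [similarity()].
#' @param k0 Number of clusters, between 1 and K.
#' @return Integer vector of cluster labels in `1..k0`, numbered by first
#'   appearance.
#' @export
hierarchical_cut <- function(W, k0) {
  K <- ncol(W)
  if (!is.numeric(k0) || length(k0) != 1L || k0 < 1 || k0 > K)
    stop(sprintf("`k0` must lie in 1..%d", K))
  hc <- hclust(as.dist(1 - W), method = "complete")
  .cut_merge_tree(hc$merge, K, as.integer(k0))
}

#' Network modularity of a phenotype partition
#'
#' Newman-Girvan modularity of the weighted network `W` under the partition
#' given by `labels`:
#' `Q = (1/2D) * sum_{j,k} (W[j,k] - d[j] d[k] / (2D)) * C[j,k]`,
#' where `d[j]` is the total degree of node j (row sum of `W`, self-loop
#' included), `2D = sum(d)`, and `C[j,k] = 1` when j and k share a cluster.
#' The sum runs over all ordered pairs including `j = k`. The one-cluster
#' partition has `Q = 0` exactly.
#'
#' @param W Similarity matrix.
#' @param labels Integer cluster labels, one per phenotype.
#' @return Scalar modularity `Q` (at most 1).
#' @export
modularity <- function(W, labels) {
  W <- as.matrix(W)
  if (length(labels) != ncol(W))
    stop("`labels` length must equal the number of phenotypes")
  d <- rowSums(W)
  twoD <- sum(d)
  if (twoD <= 0) stop("modularity undefined: network has no edges")
  B <- W - tcrossprod(d) / twoD
  lab <- as.integer(factor(labels))
  S <- rowsum(B, lab, reorder = FALSE)
  sum(diag(rowsum(t(S), lab, reorder = FALSE))) / twoD
}

#' Select the phenotype clustering that maximises modularity
#'
#' Evaluates every cut `k0 = 1..K` of the complete-linkage dendrogram over
#' `1 - W`, scores each by [modularity()], and returns the cut with maximal
#' `Q` (ties broken toward fewer clusters).
#'
#' @param W Similarity matrix from [similarity()].
#' @return Object of class `cluster_assignment`: list with `labels`
#'   (length-K integer labels in `1..L`), `L`, `Q` (the attained maximum)
#'   and `modularity_curve` (the Q value at every `k0`).
#' @export
select_clusters <- function(W) {
  W <- as.matrix(W)
  K <- ncol(W)
  if (K < 2L) stop("need at least two phenotypes")
  if (sum(W) <= 0) stop("modularity undefined: network has no edges")
  hc <- hclust(as.dist(1 - W), method = "complete")
  curve <- .modularity_curve(W, hc)
  # smallest k0 on ties; tolerance absorbs floating-point noise in the
  # incremental curve (exact ties arise for degenerate W)
  L <- which(curve >= max(curve) - 1e-12)[1]
  structure(list(labels = .cut_merge_tree(hc$merge, K, L),
                 L = as.integer(L), Q = curve[L],
                 modularity_curve = curve),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Phenotype clustering: K = %d phenotypes in L = %d clusters (Q = %.4f)\n",
              length(x$labels), x$L, x$Q))
  cat("cluster sizes:", tabulate(x$labels, x$L), "\n")
  invisible(x)
}

#' Merge clustered phenotypes by logical union
#'
#' Column l of the merged matrix is the element-wise maximum of the member
#' phenotypes of cluster l: an individual is a case for the merged phenotype
#' when they are a case for any member. Merging raises the case-control
#' ratio of each merged phenotype relative to its members.
#'
#' @param phenos n x K binary phenotype matrix.
#' @param assignment A `cluster_assignment` from [select_clusters()], or a
#'   bare integer label vector.
#' @return n x L binary matrix with attribute `cluster_sizes`.
#' @export
merge_phenotypes <- function(phenos, assignment) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else as.integer(assignment)
  Y <- as.matrix(phenos)
  if (length(labels) != ncol(Y))
    stop("label length must equal the number of phenotype columns")
  L <- max(labels)
  merged <- vapply(seq_len(L), function(l) {
    as.integer(rowSums(Y[, labels == l, drop = FALSE]) > 0)
  }, integer(nrow(Y)))
  colnames(merged) <- paste0("cluster", seq_len(L))
  attr(merged, "cluster_sizes") <- tabulate(labels, L)
  merged
}
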