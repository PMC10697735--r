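#' Read a phenotype, genotype or covariate matrix from tab-delimited text
#'
#' Reads the package's exchange dialect: a header row, a first column of
#' individual IDs, and one column per phenotype/SNP/covariate. Validation
#' depends on `kind`:
#'
#' * `"phenotype"` — entries must be 0 or 1; offending cells are reported
#'   by row ID and column name.
#' * `"genotype"` — entries must be 0, 1, 2 or missing (`NA`); rows with a
#'   missing genotype are dropped with a message reporting the count.
#'   PLINK additive-dosage exports (`--recode A` `.raw` files, whose header
#'   starts `FID IID PAT MAT SEX PHENOTYPE ...`) are detected and the six
#'   pedigree columns skipped, with `IID` used as the row ID.
#' * `"covariate"` — any finite numeric values.
#'
#' @param path File path.
#' @param kind One of `"phenotype"`, `"genotype"`, `"covariate"`.
#' @return Numeric matrix with individual IDs as row names.
#' @export
io_read_matrix <- function(path, kind = c("phenotype", "genotype", "covariate")) {
  kind <- match.arg(kind)
  header <- strsplit(readLines(path, n = 1L), "[\t ]+")[[1]]
  plink <- kind == "genotype" && length(header) >= 6 &&
    identical(toupper(header[1:2]), c("FID", "IID"))
  if (plink) {
    df <- read.table(path, header = TRUE, sep = "", check.names = FALSE,
                     stringsAsFactors = FALSE)
    ids <- as.character(df[["IID"]])
    M <- as.matrix(df[, -(1:6), drop = FALSE])
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    M <- as.matrix(df[, -1, drop = FALSE])
  }
  if (!is.numeric(M)) stop("non-numeric entries in ", path)
  rownames(M) <- ids
  if (anyDuplicated(ids))
    stop("duplicated individual IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (kind == "phenotype") {
    bad <- which(!(M == 0 | M == 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-binary phenotype value %g at row %s, column %s",
                   M[bad[1, , drop = FALSE]], ids[bad[1, 1]],
                   colnames(M)[bad[1, 2]]))
    storage.mode(M) <- "integer"
  } else if (kind == "genotype") {
    ok <- is.na(M) | M == 0 | M == 1 | M == 2
    if (!all(ok)) {
      bad <- which(!ok, arr.ind = TRUE)
      stop(sprintf("genotype value %g outside {0,1,2,NA} at row %s, column %s",
                   M[bad[1, , drop = FALSE]], ids[bad[1, 1]],
                   colnames(M)[bad[1, 2]]))
    }
    drop_rows <- !complete.cases(M)
    if (any(drop_rows)) {
      message("dropping ", sum(drop_rows), " individual(s) with missing genotypes")
      M <- M[!drop_rows, , drop = FALSE]
    }
  } else {
    if (any(!is.finite(M))) stop("non-finite covariate values in ", path)
  }
  M
}

#' Write a matrix in the package's tab-delimited exchange dialect
#'
#' Header row of `id` followed by column names; one row per individual.
#' [io_read_matrix()] reads the result back bit-identically.
#'
#' @param x Matrix (row names used as IDs; generated when absent).
#' @param path Output file path.
#' @param id_col Name of the leading ID column.
#' @export
io_write_matrix <- function(x, path, id_col = "IID") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("ind", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  df <- data.frame(rownames(x), x, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align matrices on shared individual IDs
#'
#' Checks that every matrix covers the same individuals and returns them
#' reordered to the ID order of the first; IDs present in one file but not
#' another are an explicit error naming the offenders.
#'
#' @param ... Named matrices with individual IDs as row names.
#' @return List of matrices in consistent row order.
#' @export
io_align_ids <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1)
  ids <- rownames(mats[[1]])
  for (i in seq_along(mats)[-1]) {
    other <- rownames(mats[[i]])
    miss <- setdiff(ids, other)
    extra <- setdiff(other, ids)
    if (length(miss) || length(extra))
      stop("individual IDs do not match between inputs; missing: ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(extra)) paste0("; unexpected: ",
                                     paste(utils::head(extra, 5), collapse = ", ")))
    mats[[i]] <- mats[[i]][ids, , drop = FALSE]
  }
  mats
}

#' Export a cluster assignment and its modularity curve
#'
#' Writes the phenotype-to-cluster table as two tab-delimited columns
#' (`phenotype`, `cluster`) and, optionally, the modularity value at every
#' candidate cluster count as (`k0`, `Q`) pairs.
#'
#' @param assignment A `cluster_assignment` from [select_clusters()].
#' @param path Output path for the assignment table.
#' @param phenotype_names Optional phenotype names (defaults to `pheno<k>`).
#' @param curve_path Optional output path for the modularity curve.
#' @export
io_write_assignment <- function(assignment, path, phenotype_names = NULL,
                                curve_path = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  K <- length(assignment$labels)
  if (is.null(phenotype_names)) phenotype_names <- paste0("pheno", seq_len(K))
  write.table(data.frame(phenotype = phenotype_names,
                         cluster = assignment$labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(curve_path))
    write.table(data.frame(k0 = seq_len(K), Q = assignment$modularity_curve),
                curve_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-SNP association scan over a genotype matrix
#'
#' Applies [mln_o_test()] (and optionally the comparator tests) to each
#' column of a genotype matrix against one shared phenotype matrix; the
#' real-data entry point behind the command-line interface.
#'
#' @param genotypes n x S numeric matrix of minor-allele counts.
#' @param phenos n x K binary phenotype matrix.
#' @param covars Optional covariate matrix.
#' @param methods Methods to run (default MLN-O only; comparators accept no
#'   covariates and are run on the unadjusted phenotypes).
#' @return Data frame with one row per SNP and method: `snp`, `method`,
#'   `statistic`, `df`, `p_value`, `clusters`.
#' @export
mlno_scan <- function(genotypes, phenos, covars = NULL, methods = "MLN-O") {
  G <- as.matrix(genotypes)
  methods <- match.arg(methods, .mlno_methods, several.ok = TRUE)
  snps <- colnames(G)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(G)))
  rows <- lapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    do.call(rbind, lapply(methods, function(mth) {
      res <- tryCatch(switch(mth,
        "MLN-O" = {
          r <- mln_o_test(x, phenos, covars)
          data.frame(statistic = r$statistic, df = r$df,
                     p_value = r$p_value, clusters = r$df)
        },
        "MANOVA" = { r <- manova_test(x, phenos)
          data.frame(statistic = r$statistic, df = r$df,
                     p_value = r$p_value, clusters = NA) },
        "USAT" = { r <- usat_test(x, phenos)
          data.frame(statistic = r$statistic, df = NA,
                     p_value = r$p_value, clusters = NA) },
        "TATES" = { r <- tates_test(x, phenos)
          data.frame(statistic = r$statistic, df = NA,
                     p_value = r$p_value, clusters = NA) },
        "MultiPhen" = { r <- multiphen_test(x, phenos)
          data.frame(statistic = r$statistic, df = r$df,
                     p_value = r$p_value, clusters = NA) }),
        error = function(e) data.frame(statistic = NA, df = NA,
                                       p_value = NA, clusters = NA))
      cbind(data.frame(snp = snps[j], method = mth), res)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
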