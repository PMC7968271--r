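#' Relationship matrix container
#'
#' Symmetric cow-by-cow similarity matrix with a provenance tag: spectral
#' (S), genomic (G, VanRaden method 1) or pedigree (A, numerator
#' relationship matrix).
#'
#' @param values symmetric numeric matrix.
#' @param kind one of `"spectral"`, `"genomic"`, `"pedigree"`.
#' @param ids individual identifiers (default row names).
#' @param meta optional list of construction metadata (e.g. allele
#'   frequencies and scaling denominator for a genomic kernel).
#' @return object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(values, kind, ids = rownames(values),
                                meta = list()) {
  kind <- match.arg(kind, c("spectral", "genomic", "pedigree"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > 1e-8)
    stop("relationship matrix is not symmetric")
  values <- (values + t(values)) / 2
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(values)))
  ids <- as.character(ids)
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, kind = kind, ids = ids, meta = meta),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix:%s> %d x %d, mean diag %.3f\n",
              x$kind, nrow(x$values), ncol(x$values),
              mean(diag(x$values))))
  invisible(x)
}

#' @export
as.matrix.relationship_matrix <- function(x, ...) x$values

#' Subset a relationship matrix to a set of individuals
#' @param k a [relationship_matrix()].
#' @param ids identifiers to keep (order respected).
#' @return a [relationship_matrix()] over `ids`.
#' @export
subset_kernel <- function(k, ids) {
  ids <- as.character(ids)
  if (!all(ids %in% k$ids)) stop("unknown ids in kernel subset")
  relationship_matrix(k$values[ids, ids, drop = FALSE], k$kind, ids,
                      meta = k$meta)
}

#' Spectral relationship matrix S
#'
#' S = W W' / m, where W is the column-centered and standardized wavenumber
#' matrix. With all columns kept and unbiased (n-1) standardization,
#' trace(S) = n - 1 and the row sums are zero.
#'
#' @param w standardized spectra matrix (rows = cows), e.g. the `values`
#'   element of [standardize_columns()].
#' @param m_total divisor; defaults to `ncol(w)`. Pass the pre-drop channel
#'   count when constant wavenumbers were removed during standardization.
#' @param ids cow ids (default row names of `w`).
#' @return a `"spectral"` [relationship_matrix()].
#' @export
spectral_kernel <- function(w, m_total = ncol(w), ids = rownames(w)) {
  w <- as.matrix(w)
  if (nrow(w) < 2) stop("at least two cows are required")
  if (ncol(w) < 1) stop("no informative wavenumbers")
  S <- tcrossprod(w) / m_total
  relationship_matrix(S, "spectral", ids = ids,
                      meta = list(m_total = m_total, m_kept = ncol(w)))
}

#' Genomic relationship matrix G (VanRaden method 1)
#'
#' G = Z Z' / (2 sum p_j (1 - p_j)) with Z = dosages - 2 p. Allele
#' frequencies default to those observed in the (imputed) construction set.
#'
#' @param g a complete (imputed) [genotype_matrix()], or a plain dosage
#'   matrix.
#' @param p optional reference-allele frequencies; computed from `g` when
#'   omitted.
#' @return a `"genomic"` [relationship_matrix()] whose `meta` stores `p`,
#'   the scaling `denom` and `snp_ids` (needed to back-solve SNP effects).
#' @export
genomic_kernel <- function(g, p = NULL) {
  if (inherits(g, "genotype_matrix")) {
    d <- g$dosages; ids <- g$cow_ids; snp_ids <- g$snp_ids
  } else {
    d <- as.matrix(g); ids <- rownames(d); snp_ids <- colnames(d)
  }
  if (anyNA(d)) stop("genotypes must be imputed before kernel construction")
  if (is.null(p)) p <- colMeans(d) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP present (allele frequency 0 or 1); ",
         "filter with genotype_qc first")
  Z <- sweep(d, 2, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  relationship_matrix(G, "genomic", ids = ids,
                      meta = list(p = p, denom = denom, snp_ids = snp_ids))
}

#' Pedigree (numerator) relationship matrix A
#'
#' Recursive tabular method over a topological ordering of the full
#' pedigree; the result is restricted to `subset` only after construction,
#' so ancestors always contribute. Diagonal entries equal 1 + F (inbreeding
#' coefficient).
#'
#' @param ped a [pedigree()] (or coercible data frame).
#' @param subset ids to retain (default: all individuals).
#' @return a `"pedigree"` [relationship_matrix()].
#' @export
pedigree_kernel <- function(ped, subset = NULL) {
  ped <- pedigree(ped)
  ord <- pedigree_order(ped)
  ped <- ped[ord, , drop = FALSE]
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      prev <- seq_len(i - 1)
      rs <- if (s > 0) A[s, prev] else 0
      rd <- if (d > 0) A[d, prev] else 0
      A[i, prev] <- 0.5 * (rs + rd)
      A[prev, i] <- A[i, prev]
    }
    Asd <- if (s > 0 && d > 0) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * Asd
  }
  dimnames(A) <- list(ped$id, ped$id)
  if (is.null(subset)) subset <- ped$id
  subset <- as.character(subset)
  if (!all(subset %in% ped$id))
    stop("subset ids missing from pedigree: ",
         paste(head(setdiff(subset, ped$id), 5), collapse = ", "))
  relationship_matrix(A[subset, subset, drop = FALSE], "pedigree",
                      ids = subset)
}

#' Write/read a relationship matrix as delimited text
#' @param k a [relationship_matrix()].
#' @param path file path.
#' @param kind kind tag used when reading back.
#' @name kernel_io
NULL

#' @rdname kernel_io
#' @export
write_kernel <- function(k, path) {
  write_matrix_csv(k$values, path, id_col = "id")
  invisible(path)
}

#' @rdname kernel_io
#' @export
read_kernel <- function(path, kind) {
  m <- read_matrix_csv(path)
  colnames(m) <- rownames(m)
  relationship_matrix(m, kind, ids = rownames(m))
}
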