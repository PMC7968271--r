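#' Spectra matrix
#'
#' Container for milk FTIR absorbance spectra: one row per cow, one column
#' per wavenumber channel (cm^-1). Wavenumbers must be strictly monotone
#' (FTIR instruments report them in descending order) and no entry may be
#' missing after acquisition averaging.
#'
#' @param values numeric matrix, cows x wavenumbers.
#' @param wavenumbers numeric vector of channel labels in cm^-1; defaults to
#'   the numeric column names of `values`.
#' @param cow_ids character vector of cow identifiers; defaults to row names.
#' @return An object of class `spectra_matrix` with fields `values`,
#'   `wavenumbers`, `cow_ids`.
#' @export
spectra_matrix <- function(values,
                           wavenumbers = as.numeric(colnames(values)),
                           cow_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(cow_ids)) cow_ids <- paste0("cow", seq_len(nrow(values)))
  cow_ids <- as.character(cow_ids)
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(values))
    stop("wavenumbers must label every column")
  if (ncol(values) < 1L) stop("at least one wavenumber is required")
  if (anyNA(values)) stop("spectra contain missing values")
  dw <- diff(wavenumbers)
  if (length(dw) && !(all(dw > 0) || all(dw < 0)))
    stop("wavenumbers must be strictly monotone")
  if (anyDuplicated(cow_ids)) stop("duplicated cow ids")
  dimnames(values) <- list(cow_ids, format(wavenumbers, trim = TRUE))
  structure(list(values = values, wavenumbers = wavenumbers,
                 cow_ids = cow_ids),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d cows x %d wavenumbers (%.0f-%.0f cm^-1)\n",
              nrow(x$values), ncol(x$values),
              x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)]))
  invisible(x)
}

#' Genotype matrix
#'
#' SNP dosages coded 0/1/2 (copies of the reference allele), with missing
#' calls stored as `NA`. Any negative value or `NA` in the input is treated
#' as missing.
#'
#' @param dosages numeric matrix, cows x SNPs.
#' @param snp_ids,cow_ids identifiers; default to dimnames.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages,
                            snp_ids = colnames(dosages),
                            cow_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  if (is.null(cow_ids)) cow_ids <- paste0("cow", seq_len(nrow(dosages)))
  dosages[!is.na(dosages) & dosages < 0] <- NA
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing")
  dimnames(dosages) <- list(as.character(cow_ids), as.character(snp_ids))
  structure(list(dosages = dosages,
                 snp_ids = as.character(snp_ids),
                 cow_ids = as.character(cow_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d cows x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Reference allele frequencies from observed calls
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector, per-SNP frequency of the reference allele among
#'   non-missing calls.
#' @export
allele_freq <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  colMeans(g$dosages, na.rm = TRUE) / 2
}

#' Pedigree
#'
#' Three-column pedigree (individual, sire, dam). Unknown parents may be
#' coded `NA`, `"0"` or `""`. Parents that appear only as sire/dam are
#' appended as founder records.
#'
#' @param records data frame with columns `id`, `sire`, `dam` (first three
#'   columns are used positionally).
#' @return Object of class `pedigree`: a data frame with character columns
#'   `id`, `sire`, `dam` (`NA` = unknown).
#' @export
pedigree <- function(records) {
  records <- as.data.frame(records)
  if (ncol(records) < 3) stop("pedigree needs id, sire, dam columns")
  ped <- data.frame(id = as.character(records[[1]]),
                    sire = as.character(records[[2]]),
                    dam = as.character(records[[3]]),
                    stringsAsFactors = FALSE)
  for (col in c("sire", "dam"))
    ped[[col]][ped[[col]] %in% c("0", "", "NA") | is.na(ped[[col]])] <- NA
  if (anyDuplicated(ped$id)) stop("duplicated individual ids in pedigree")
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(parents)) {
    ped <- rbind(data.frame(id = parents, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 ped)
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Topological order of a pedigree (parents before offspring); errors with
# the offending chain if a cycle exists.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  state <- integer(n)  # 0 unvisited, 1 in stack, 2 done
  order <- integer(0)
  visit <- function(i, chain) {
    if (state[i] == 1L)
      stop("pedigree cycle detected: ",
           paste(ped$id[c(chain, i)], collapse = " -> "), call. = FALSE)
    if (state[i] == 2L) return(invisible())
    state[i] <<- 1L
    for (par in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(par)) visit(idx[[par]], c(chain, i))
    }
    state[i] <<- 2L
    order <<- c(order, i)
    invisible()
  }
  for (i in seq_len(n)) if (state[i] == 0L) visit(i, integer(0))
  order
}

#' Average replicate spectral acquisitions per cow
#'
#' Each milk sample is scanned more than once; replicate spectra are
#' averaged per cow before analysis.
#'
#' @param raw named list (names = cow ids); each element a matrix of
#'   replicates x wavenumbers with identical numeric column names across
#'   cows, or a numeric vector for a single acquisition.
#' @return A [spectra_matrix()] of per-cow mean spectra.
#' @export
average_acquisitions <- function(raw) {
  if (!length(raw) || is.null(names(raw)))
    stop("raw must be a named list of per-cow replicate matrices")
  first <- raw[[1]]
  if (is.vector(first)) first <- matrix(first, nrow = 1,
                                        dimnames = list(NULL, names(raw[[1]])))
  grid <- colnames(first)
  if (is.null(grid)) stop("replicates must carry wavenumber column names")
  out <- matrix(NA_real_, length(raw), length(grid),
                dimnames = list(names(raw), grid))
  for (cow in names(raw)) {
    rep <- raw[[cow]]
    if (is.vector(rep)) rep <- matrix(rep, nrow = 1,
                                      dimnames = list(NULL, names(raw[[cow]])))
    if (is.null(colnames(rep)) || !identical(colnames(rep), grid))
      stop("wavenumber grid mismatch for cow '", cow, "'")
    if (nrow(rep) < 1) stop("cow '", cow, "' has no acquisitions")
    out[cow, ] <- colMeans(rep)
  }
  spectra_matrix(out, wavenumbers = as.numeric(grid), cow_ids = names(raw))
}

#' Genotype quality control
#'
#' Removes SNPs whose call rate or minor allele frequency falls strictly
#' below the thresholds (values exactly at a threshold are kept).
#'
#' @param g a [genotype_matrix()].
#' @param call_rate_min minimum call rate retained (default 0.95).
#' @param maf_min minimum minor allele frequency retained (default 0.05).
#' @return list with elements `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (data frame: snp, call_rate, maf, removed, reason).
#' @export
genotype_qc <- function(g, call_rate_min = 0.95, maf_min = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  call_rate <- colMeans(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing SNP: no information
  fail_cr <- call_rate < call_rate_min
  fail_maf <- maf < maf_min
  removed <- fail_cr | fail_maf
  reason <- rep(NA_character_, ncol(d))
  reason[fail_maf] <- "maf"
  reason[fail_cr] <- "call_rate"
  reason[fail_cr & fail_maf] <- "call_rate+maf"
  report <- data.frame(snp = g$snp_ids, call_rate = call_rate, maf = maf,
                       removed = removed, reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (all(removed))
    stop("no SNPs survive quality control (empty panel)")
  keep <- !removed
  list(genotypes = genotype_matrix(d[, keep, drop = FALSE],
                                   snp_ids = g$snp_ids[keep],
                                   cow_ids = g$cow_ids),
       report = report)
}

#' Impute missing genotypes from allele frequencies
#'
#' Each missing dosage is replaced by a draw from Binomial(2, p_ref), where
#' p_ref is the reference-allele frequency of that SNP among observed calls.
#' Observed calls are never altered.
#'
#' @param g a [genotype_matrix()].
#' @param seed integer seed; the imputation is deterministic given the seed.
#' @return A complete [genotype_matrix()].
#' @export
impute_genotypes <- function(g, seed) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  if (anyNA(p) || any(is.nan(p)))
    stop("SNP with all calls missing: allele frequency undefined (",
         paste(head(g$snp_ids[is.nan(p) | is.na(p)], 5), collapse = ", "), ")")
  miss <- which(is.na(d), arr.ind = TRUE)
  if (nrow(miss)) {
    withr::with_seed(seed, {
      d[miss] <- stats::rbinom(nrow(miss), 2, p[miss[, 2]])
    })
  }
  genotype_matrix(d, snp_ids = g$snp_ids, cow_ids = g$cow_ids)
}

#' Flag spectral outliers by Mahalanobis distance in PC space
#'
#' Principal component analysis of the spectra followed by a chi-square
#' screen on the Mahalanobis distance of each cow in the retained component
#' space. Cows are flagged only, never removed.
#'
#' @param s a [spectra_matrix()].
#' @param n_components number of principal components retained.
#' @param distance_quantile chi-square quantile above which a cow is flagged
#'   (default 0.99).
#' @return character vector of flagged cow ids, with attribute `distance`
#'   (named squared Mahalanobis distances) and `cutoff`.
#' @export
spectral_outlier_screen <- function(s, n_components, distance_quantile = 0.99) {
  stopifnot(inherits(s, "spectra_matrix"))
  n <- nrow(s$values)
  if (n_components >= min(n, ncol(s$values)))
    stop("n_components must be < min(n_cows, n_wavenumbers)")
  pc <- stats::prcomp(s$values, center = TRUE, scale. = FALSE)
  ev <- pc$sdev[seq_len(n_components)]^2
  if (any(ev <= 1e-12))
    stop("singular PC covariance; use fewer components")
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  d2 <- rowSums(sweep(scores^2, 2, ev, "/"))
  cutoff <- stats::qchisq(distance_quantile, df = n_components)
  flagged <- s$cow_ids[d2 > cutoff]
  names(d2) <- s$cow_ids
  structure(flagged, distance = d2, cutoff = cutoff)
}

#' Center and scale matrix columns using statistics from a row subset
#'
#' Column means and unit sample standard deviations (n-1 denominator) are
#' computed on `stats_from` rows and applied to all rows, so the same
#' statistics can transform held-out rows without leakage. Columns with
#' (near-)zero variance on the `stats_from` rows are dropped with a warning.
#'
#' @param m numeric matrix.
#' @param stats_from row indices used to compute the statistics (default all).
#' @param tol variance tolerance below which a column counts as constant.
#' @return list: `values` (transformed matrix, kept columns), `center`,
#'   `scale`, `kept` (logical over original columns), `dropped` (names/indices).
#' @export
standardize_columns <- function(m, stats_from = seq_len(nrow(m)), tol = 1e-12) {
  m <- as.matrix(m)
  sub <- m[stats_from, , drop = FALSE]
  center <- colMeans(sub)
  scale <- apply(sub, 2, stats::sd)
  kept <- !is.na(scale) & scale > sqrt(tol)
  if (!all(kept)) {
    dropped <- if (!is.null(colnames(m))) colnames(m)[!kept] else which(!kept)
    warning(sum(!kept), " constant column(s) dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (sum(!kept) > 5) ", ..." else "")
  } else dropped <- character(0)
  values <- sweep(sweep(m[, kept, drop = FALSE], 2, center[kept], "-"),
                  2, scale[kept], "/")
  list(values = values, center = center[kept], scale = scale[kept],
       kept = kept, dropped = dropped)
}

#' Apply previously computed column statistics to new rows
#'
#' @param m matrix whose columns match the columns kept by
#'   [standardize_columns()] (matched by name when available).
#' @param stats result of [standardize_columns()].
#' @return transformed matrix.
#' @export
apply_column_stats <- function(m, stats) {
  m <- as.matrix(m)
  if (!is.null(colnames(m)) && !is.null(names(stats$center))) {
    if (!all(names(stats$center) %in% colnames(m)))
      stop("columns missing from new data")
    m <- m[, names(stats$center), drop = FALSE]
  } else if (ncol(m) == length(stats$kept)) {
    m <- m[, stats$kept, drop = FALSE]
  } else if (ncol(m) != length(stats$center)) {
    stop("column count mismatch with stored statistics")
  }
  sweep(sweep(m, 2, stats$center, "-"), 2, stats$scale, "/")
}

#' Assemble and reconcile the study tables into one bundle
#'
#' Joins the five tables on cow id. Joins are strict: any cow missing from
#' one table aborts with a reconciliation report.
#'
#' @param spectra [spectra_matrix()].
#' @param genotypes [genotype_matrix()] (optional, `NULL` allowed).
#' @param ped [pedigree()] (optional).
#' @param onfarm data frame with columns `cow_id`, `herd`, `dim`, `parity`.
#' @param traits numeric matrix of traits, rows named by cow id.
#' @return list of class `cow_bundle`, rows aligned to `spectra$cow_ids`.
#' @export
cow_bundle <- function(spectra, genotypes = NULL, ped = NULL, onfarm, traits) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  ids <- spectra$cow_ids
  tables <- list(onfarm = as.character(onfarm$cow_id),
                 traits = rownames(traits))
  if (!is.null(genotypes)) tables$genotypes <- genotypes$cow_ids
  bad <- lapply(tables, function(x) setdiff(ids, x))
  extra <- lapply(tables, function(x) setdiff(x, ids))
  if (any(lengths(bad) > 0) || any(lengths(extra) > 0)) {
    msg <- c()
    for (nm in names(tables)) {
      if (length(bad[[nm]]))
        msg <- c(msg, sprintf("%s missing %d cow(s): %s", nm,
                              length(bad[[nm]]),
                              paste(head(bad[[nm]], 5), collapse = ", ")))
      if (length(extra[[nm]]))
        msg <- c(msg, sprintf("%s has %d unknown cow(s): %s", nm,
                              length(extra[[nm]]),
                              paste(head(extra[[nm]], 5), collapse = ", ")))
    }
    stop("cow id reconciliation failed:\n  ", paste(msg, collapse = "\n  "))
  }
  onfarm <- onfarm[match(ids, onfarm$cow_id), , drop = FALSE]
  stopifnot(all(c("herd", "dim", "parity") %in% names(onfarm)))
  if (any(onfarm$dim < 0)) stop("negative days in milk")
  if (any(onfarm$parity < 1)) stop("parity must be a positive integer")
  traits <- as.matrix(traits)[ids, , drop = FALSE]
  if (anyNA(traits)) stop("traits contain missing values")
  if (!is.null(genotypes)) {
    keep <- match(ids, genotypes$cow_ids)
    genotypes <- genotype_matrix(genotypes$dosages[keep, , drop = FALSE],
                                 snp_ids = genotypes$snp_ids, cow_ids = ids)
  }
  if (!is.null(ped)) {
    ped <- pedigree(ped)
    if (!all(ids %in% ped$id))
      stop("pedigree missing cow(s): ",
           paste(head(setdiff(ids, ped$id), 5), collapse = ", "))
  }
  structure(list(spectra = spectra, genotypes = genotypes, pedigree = ped,
                 onfarm = onfarm, traits = traits, cow_ids = ids),
            class = "cow_bundle")
}

#' @export
print.cow_bundle <- function(x, ...) {
  cat(sprintf(
    "<cow_bundle> %d cows, %d wavenumbers, %s SNPs, %d herds, %d traits\n",
    length(x$cow_ids), ncol(x$spectra$values),
    if (is.null(x$genotypes)) "no" else ncol(x$genotypes$dosages),
    length(unique(x$onfarm$herd)), ncol(x$traits)))
  invisible(x)
}

# ---- delimited text I/O -----------------------------------------------------

read_matrix_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

write_matrix_csv <- function(m, path, id_col = "cow_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path)
}

#' Read study tables from delimited text
#'
#' Matrices (spectra, genotypes, traits) are CSV with a header row of
#' wavenumber/SNP/trait labels and a first column of cow ids. The pedigree
#' is 3-column text (id, sire, dam; "0" = unknown).
#'
#' @param path file path.
#' @return the corresponding container object.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_spectra <- function(path) {
  m <- read_matrix_csv(path)
  spectra_matrix(m, wavenumbers = as.numeric(colnames(m)))
}

#' @rdname read_tables
#' @export
read_genotypes <- function(path) {
  m <- read_matrix_csv(path)
  genotype_matrix(m)
}

#' @rdname read_tables
#' @export
read_pedigree <- function(path) {
  pedigree(data.table::fread(path, header = TRUE, data.table = FALSE,
                             colClasses = "character"))
}

#' @rdname read_tables
#' @export
read_onfarm <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  df$cow_id <- as.character(df$cow_id)
  df$herd <- as.character(df$herd)
  df
}

#' @rdname read_tables
#' @export
read_traits <- function(path) read_matrix_csv(path)
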