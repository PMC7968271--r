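#' The seven-model covariate catalogue
#'
#' Returns the admissible method x model combinations and the covariates
#' each model carries. The kernel method admits M1-M7; BayesB admits M1-M4
#' (it performs variable selection internally, so the top-marker models are
#' not defined for it); PLS admits M1-M4 and M7.
#'
#' @return data frame with columns `model`, `method` and logical covariate
#'   flags (`herd`, `dim`, `parity`, `ftir`, `genomics`, `top_markers`,
#'   `pedigree`).
#' @export
model_catalogue <- function() {
  flags <- data.frame(
    model = paste0("M", 1:7),
    herd = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    dim = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    parity = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    ftir = TRUE,
    genomics = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    top_markers = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    pedigree = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  allowed <- rbind(
    data.frame(method = "kernel", model = paste0("M", 1:7)),
    data.frame(method = "bayesb", model = paste0("M", 1:4)),
    data.frame(method = "pls", model = paste0("M", c(1:4, 7))))
  out <- merge(allowed, flags, by = "model", sort = FALSE)
  out[order(out$method, out$model), c("model", "method", "herd", "dim",
                                      "parity", "ftir", "genomics",
                                      "top_markers", "pedigree")]
}

#' Construct (and validate) a catalogue entry
#'
#' @param model_id one of `"M1"`..`"M7"`.
#' @param method one of `"kernel"`, `"bayesb"`, `"pls"`.
#' @param drop_herd strip the herd effect (herd-blocked cross-validation).
#' @return list of class `catalogue_entry` with the covariate flags.
#' @export
catalogue_entry <- function(model_id, method, drop_herd = FALSE) {
  cat_tab <- model_catalogue()
  row <- cat_tab[cat_tab$model == model_id & cat_tab$method == method, ]
  if (nrow(row) == 0)
    stop("model ", model_id, " with method '", method,
         "' is not in the model catalogue")
  entry <- as.list(row)
  if (drop_herd) entry$herd <- FALSE
  entry$drop_herd <- drop_herd
  structure(entry, class = "catalogue_entry")
}

#' Select the top-k SNPs by absolute effect size
#'
#' Markers are ranked by |effect|; ties are broken by panel order (a
#' logged, deterministic rule). For a kernel-model fit the effects are the
#' GBLUP back-solution; for a BayesB fit they are the SNP-layer posterior
#' means.
#'
#' @param effects named numeric vector of marker effects, or a `kernel_fit`
#'   (with `G` and `g` supplied) or `bayesb_fit`.
#' @param k number of markers to select (default 3).
#' @param ... passed to [backsolve_snp_effects()] for kernel fits
#'   (`G`, `g`, `kernel_name`).
#' @return list: `ids`, `effects` (the selected markers, in rank order).
#' @export
select_top_snps <- function(effects, k = 3, ...) {
  if (inherits(effects, "kernel_fit"))
    effects <- backsolve_snp_effects(effects, ...)
  else if (inherits(effects, "bayesb_fit"))
    effects <- effects$a_hat[["SNP"]]
  if (is.null(names(effects)))
    names(effects) <- paste0("snp", seq_along(effects))
  if (k > length(effects))
    stop("k exceeds the SNP panel size")
  if (all(effects == 0))
    warning("all marker effects are zero; selecting the first ", k,
            " markers by panel order")
  ord <- order(-abs(effects), seq_along(effects))[seq_len(k)]
  list(ids = names(effects)[ord], effects = effects[ord])
}

# Fixed-effect design for one catalogue entry. Levels (herd, parity) come
# from the training rows; test rows with unseen levels get all-zero dummies
# (the reference-centered mean effect) and are counted in attr "n_unseen".
build_fixed_design <- function(onfarm, entry, train_idx, snp3 = NULL) {
  n <- nrow(onfarm)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  n_unseen <- 0L
  if (isTRUE(entry$herd)) {
    lev <- sort(unique(as.character(onfarm$herd[train_idx])))
    h <- as.character(onfarm$herd)
    n_unseen <- n_unseen + sum(!h %in% lev)
    if (length(lev) > 1) {
      H <- vapply(lev[-1], function(l) as.numeric(h == l), numeric(n))
      colnames(H) <- paste0("herd_", lev[-1])
      X <- cbind(X, H)
    }
  }
  if (isTRUE(entry$dim))
    X <- cbind(X, dim = as.numeric(onfarm$dim))
  if (isTRUE(entry$parity)) {
    lev <- sort(unique(onfarm$parity[train_idx]))
    pvals <- onfarm$parity
    n_unseen <- n_unseen + sum(!pvals %in% lev)
    if (length(lev) > 1) {
      P <- vapply(lev[-1], function(l) as.numeric(pvals == l), numeric(n))
      colnames(P) <- paste0("parity_", lev[-1])
      X <- cbind(X, P)
    }
  }
  if (!is.null(snp3)) {
    ctr <- colMeans(snp3[train_idx, , drop = FALSE])
    S3 <- sweep(as.matrix(snp3), 2, ctr, "-")
    colnames(S3) <- paste0("top_", colnames(snp3))
    X <- cbind(X, S3)
  }
  if (n_unseen > 0)
    message(n_unseen, " test-row level(s) unseen in training mapped to the ",
            "reference-centered mean effect")
  attr(X, "n_unseen") <- n_unseen
  X
}

#' Assemble the inputs for one catalogue model
#'
#' Wires the fixed-effect design, kernels, BayesB layers or PLS predictor
#' blocks for a single method x model combination, honouring the
#' training/test split (standardization statistics come from the training
#' rows unless `standardize_scope = "full"`).
#'
#' @param entry a [catalogue_entry()].
#' @param bundle a [cow_bundle()] with imputed genotypes when the model
#'   needs them.
#' @param train_idx,test_idx row indices of the split.
#' @param top_snps character vector of marker ids (required by M5/M6).
#' @param context optional precomputed pieces (list with any of `S_full`,
#'   `G_full`, `A_full`, `spectra_stats`) shared across models of one fold.
#' @param standardize_scope `"train"` (default, no leakage) or `"full"`.
#' @param pc_variance_target cumulative eigenvalue share for [pc_features()]
#'   blocks in PLS (default 0.80).
#' @return list of class `model_build` holding everything the method's fit
#'   and predict steps need.
#' @export
build_model <- function(entry, bundle, train_idx, test_idx,
                        top_snps = NULL, context = list(),
                        standardize_scope = c("train", "full"),
                        pc_variance_target = 0.80) {
  stopifnot(inherits(entry, "catalogue_entry"), inherits(bundle, "cow_bundle"))
  standardize_scope <- match.arg(standardize_scope)
  n <- length(bundle$cow_ids)
  if (entry$top_markers && is.null(top_snps))
    stop("model ", entry$model, " requires top_snps")
  if ((entry$genomics || entry$top_markers) && is.null(bundle$genotypes))
    stop("model ", entry$model, " requires genotypes")
  if (entry$pedigree && is.null(bundle$pedigree))
    stop("model ", entry$model, " requires a pedigree")
  g <- bundle$genotypes
  if (!is.null(g) && anyNA(g$dosages))
    stop("genotypes must be imputed before model building")

  # spectra standardization (training stats by default)
  st <- context$spectra_stats
  if (is.null(st)) {
    rows <- if (standardize_scope == "train") train_idx else seq_len(n)
    st <- standardize_columns(bundle$spectra$values, stats_from = rows)
  }
  W_full <- st$values

  snp3 <- NULL
  if (entry$top_markers) {
    if (!all(top_snps %in% g$snp_ids)) stop("unknown top_snps ids")
    snp3 <- g$dosages[, top_snps, drop = FALSE]
  }
  X_full <- build_fixed_design(bundle$onfarm, entry, train_idx, snp3 = snp3)

  out <- list(entry = entry, train_idx = train_idx, test_idx = test_idx,
              X_trn = X_full[train_idx, , drop = FALSE],
              X_tst = X_full[test_idx, , drop = FALSE],
              include_fixed = entry$model != "M1")

  if (entry$method == "kernel") {
    kernels <- list()
    S_full <- context$S_full
    if (is.null(S_full))
      S_full <- spectral_kernel(W_full, m_total = ncol(bundle$spectra$values),
                                ids = bundle$cow_ids)
    kernels$S <- S_full
    if (entry$genomics) {
      if (entry$top_markers) {  # M6: rebuild G without the top markers
        keep <- setdiff(g$snp_ids, top_snps)
        kernels$G <- genomic_kernel(
          genotype_matrix(g$dosages[, keep, drop = FALSE],
                          snp_ids = keep, cow_ids = g$cow_ids))
      } else {
        kernels$G <- if (!is.null(context$G_full)) context$G_full
                     else genomic_kernel(g)
      }
    }
    if (entry$pedigree) {
      kernels$A <- if (!is.null(context$A_full)) context$A_full
                   else pedigree_kernel(bundle$pedigree, bundle$cow_ids)
    }
    out$kernels_full <- kernels
    out$kernels_trn <- lapply(kernels, function(k)
      k$values[train_idx, train_idx, drop = FALSE])
  } else if (entry$method == "bayesb") {
    layers_trn <- layers_tst <- list()
    layers_trn$IR <- W_full[train_idx, , drop = FALSE]
    layers_tst$IR <- W_full[test_idx, , drop = FALSE]
    if (entry$genomics) {
      rows <- if (standardize_scope == "train") train_idx else seq_len(n)
      gst <- standardize_columns(g$dosages, stats_from = rows)
      layers_trn$SNP <- gst$values[train_idx, , drop = FALSE]
      layers_tst$SNP <- gst$values[test_idx, , drop = FALSE]
    }
    out$layers_trn <- layers_trn
    out$layers_tst <- layers_tst
  } else {  # pls
    blocks <- list()
    if (ncol(out$X_trn) > 1)  # one-hot/covariate columns, minus intercept
      blocks$onfarm <- X_full[, -1, drop = FALSE]
    blocks$spectra <- bundle$spectra$values
    if (entry$genomics) {
      G_full <- if (!is.null(context$G_full)) context$G_full
                else genomic_kernel(g)
      blocks$G <- pc_features(G_full, pc_variance_target)$scores
    }
    if (entry$pedigree) {
      A_full <- if (!is.null(context$A_full)) context$A_full
                else pedigree_kernel(bundle$pedigree, bundle$cow_ids)
      blocks$A <- pc_features(A_full, pc_variance_target)$scores
    }
    Xp <- do.call(cbind, blocks)
    colnames(Xp) <- make.unique(unlist(lapply(blocks, colnames)))
    out$X_pls <- Xp
  }
  class(out) <- "model_build"
  out
}

#' Fit one assembled catalogue model and predict its test rows
#'
#' Dispatches to the kernel sampler, (multilayer) BayesB or PLS according
#' to the entry's method, then applies the model's prediction formula.
#'
#' @param built a [build_model()] result.
#' @param y full-length phenotype vector (training rows are taken from it).
#' @param mcmc an [mcmc_control()] (ignored by PLS).
#' @param prior a [kernel_prior()] (kernel method only).
#' @param seed integer seed.
#' @param eigen_cache optional named eigen cache for the kernel method.
#' @param max_components,inner_folds PLS settings.
#' @return list: `fit`, `pred` (test predictions), `entry`.
#' @export
fit_catalogue_model <- function(built, y, mcmc = mcmc_control(),
                                prior = kernel_prior(), seed = 1L,
                                eigen_cache = NULL,
                                max_components = 50, inner_folds = 10) {
  stopifnot(inherits(built, "model_build"))
  entry <- built$entry
  y <- as.numeric(y)
  y_trn <- y[built$train_idx]
  if (entry$method == "kernel") {
    fit <- fit_kernel_model(y_trn, built$X_trn, built$kernels_trn,
                            prior = prior, mcmc = mcmc, seed = seed,
                            eigen_cache = eigen_cache)
    pred <- predict_kernel_testset(fit, built$kernels_full,
                                   built$train_idx, built$test_idx,
                                   X_tst = built$X_tst,
                                   include_fixed = built$include_fixed)
  } else if (entry$method == "bayesb") {
    layers <- list(layer_spec(built$layers_trn$IR, "IR"))
    if (!is.null(built$layers_trn$SNP))
      layers <- c(layers, list(layer_spec(built$layers_trn$SNP, "SNP")))
    fit <- fit_bayesb_core(y_trn, layers, built$X_trn, mcmc, seed)
    pred <- predict_bayesb(fit, X_tst = built$X_tst,
                           layer_designs = built$layers_tst,
                           include_fixed = built$include_fixed)
  } else {
    fit <- fit_pls(y_trn, built$X_pls[built$train_idx, , drop = FALSE],
                   max_components = max_components,
                   inner_folds = inner_folds, seed = seed)
    pred <- predict_pls(fit, built$X_pls[built$test_idx, , drop = FALSE])
  }
  list(fit = fit, pred = pred, entry = entry)
}
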