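#' Predictive R-squared
#'
#' Squared Pearson correlation between observed and predicted phenotypes.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3).
#' @return a number in \[0, 1\], or `NA` (with a warning) when the
#'   predictions are constant.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("at least 3 pairs are required")
  if (stats::sd(predicted) == 0) {
    warning("constant predictions: R-squared undefined")
    return(NA_real_)
  }
  stats::cor(observed, predicted)^2
}

#' Dispersion bias (regression slope)
#'
#' Coefficient from regressing observed phenotypes on predictions:
#' cov(observed, predicted) / var(predicted). A slope of 1 indicates
#' unbiased dispersion.
#'
#' @inheritParams r_squared
#' @return the slope, or `NA` (with a warning) for constant predictions.
#' @export
regression_slope <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("at least 3 pairs are required")
  if (stats::var(predicted) == 0) {
    warning("constant predictions: slope undefined")
    return(NA_real_)
  }
  stats::cov(observed, predicted) / stats::var(predicted)
}

# imputation convenience: make sure genotypes are complete
ensure_imputed <- function(bundle, seed) {
  g <- bundle$genotypes
  if (!is.null(g) && anyNA(g$dosages))
    bundle$genotypes <- impute_genotypes(g, seed = seed)
  bundle
}

needs_genomics <- function(models, methods) {
  any(models %in% c("M4", "M5", "M6")) ||
    ("bayesb" %in% methods && "M4" %in% models)
}

# shared per-repeat/method loop over traits and models
cv_one_repeat <- function(bundle, train_idx, test_idx, traits, methods,
                          models, drop_herd, mcmc, prior, seed,
                          standardize_scope, G_full, A_full,
                          max_components, inner_folds, top_k = 3) {
  n <- length(bundle$cow_ids)
  rows <- if (standardize_scope == "train") train_idx else seq_len(n)
  st <- standardize_columns(bundle$spectra$values, stats_from = rows)
  S_full <- spectral_kernel(st$values,
                            m_total = ncol(bundle$spectra$values),
                            ids = bundle$cow_ids)
  context <- list(S_full = S_full, G_full = G_full, A_full = A_full,
                  spectra_stats = st)
  # eigen cache for kernel fits shared across models/traits of this fold
  ecache <- list(S = kernel_eigen(S_full$values[train_idx, train_idx], "S"))
  if (!is.null(G_full))
    ecache$G <- kernel_eigen(G_full$values[train_idx, train_idx], "G")
  if (!is.null(A_full) && any(models == "M7"))
    ecache$A <- kernel_eigen(A_full$values[train_idx, train_idx], "A")

  res <- list()
  for (method in methods) {
    mods <- intersect(models,
                      model_catalogue()$model[model_catalogue()$method == method])
    for (trait in traits) {
      y <- bundle$traits[, trait]
      top <- NULL
      if (method == "kernel" && any(mods %in% c("M5", "M6"))) {
        # the joint spectra+genomics model selects the top markers
        e4 <- catalogue_entry("M4", "kernel", drop_herd = drop_herd)
        b4 <- build_model(e4, bundle, train_idx, test_idx, context = context,
                          standardize_scope = standardize_scope)
        f4 <- fit_catalogue_model(b4, y, mcmc = mcmc, prior = prior,
                                  seed = seed, eigen_cache = ecache)
        eff <- backsolve_snp_effects(
          f4$fit, subset_kernel(G_full, bundle$cow_ids[train_idx]),
          bundle$genotypes)
        top <- select_top_snps(eff, k = top_k)$ids
        if ("M4" %in% mods) {
          res[[length(res) + 1]] <- data.frame(
            trait = trait, method = method, model = "M4",
            r2 = r_squared(y[test_idx], f4$pred),
            slope = regression_slope(y[test_idx], f4$pred),
            n_test = length(test_idx), stringsAsFactors = FALSE)
          mods_here <- setdiff(mods, "M4")
        } else mods_here <- mods
      } else mods_here <- mods
      for (model in mods_here) {
        entry <- catalogue_entry(model, method, drop_herd = drop_herd)
        built <- build_model(entry, bundle, train_idx, test_idx,
                             top_snps = top, context = context,
                             standardize_scope = standardize_scope)
        ec <- ecache
        if (model == "M6") ec$G <- NULL  # rebuilt panel, fresh eigen
        out <- fit_catalogue_model(built, y, mcmc = mcmc, prior = prior,
                                   seed = seed, eigen_cache = ec,
                                   max_components = max_components,
                                   inner_folds = inner_folds)
        res[[length(res) + 1]] <- data.frame(
          trait = trait, method = method, model = model,
          r2 = r_squared(y[test_idx], out$pred),
          slope = regression_slope(y[test_idx], out$pred),
          n_test = length(test_idx), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, res)
}

cv_engine <- function(bundle, scheme, split_fun, traits, methods, models,
                      repeats, seed, drop_herd, mcmc, prior,
                      standardize_scope, max_components, inner_folds) {
  stopifnot(inherits(bundle, "cow_bundle"))
  cat_tab <- model_catalogue()
  if (!all(models %in% paste0("M", 1:7)))
    stop("unknown model id(s): ",
         paste(setdiff(models, paste0("M", 1:7)), collapse = ", "))
  if (!all(methods %in% c("kernel", "bayesb", "pls")))
    stop("unknown method(s)")
  requested <- unlist(lapply(methods, function(m)
    intersect(models, cat_tab$model[cat_tab$method == m])))
  if (!length(requested))
    stop("no admissible method x model combination requested")

  bundle <- ensure_imputed(bundle, seed = seed)
  G_full <- NULL
  if (needs_genomics(models, methods) && !is.null(bundle$genotypes))
    G_full <- genomic_kernel(bundle$genotypes)
  A_full <- NULL
  if ("M7" %in% models && !is.null(bundle$pedigree))
    A_full <- pedigree_kernel(bundle$pedigree, bundle$cow_ids)

  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1,
                                                 repeats))
  folds <- vector("list", repeats)
  rows <- list()
  for (r in seq_len(repeats)) {
    sp <- split_fun(rep_seeds[r])
    stopifnot(length(intersect(sp$train, sp$test)) == 0)
    folds[[r]] <- sp
    out <- cv_one_repeat(bundle, sp$train, sp$test, traits, methods, models,
                         drop_herd, mcmc, prior, rep_seeds[r],
                         standardize_scope, G_full, A_full,
                         max_components, inner_folds)
    out$rep <- r
    out$scheme <- scheme
    rows[[r]] <- out
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, scheme = scheme, seed = seed,
                 folds = folds, repeats = repeats,
                 traits = traits, methods = methods, models = models),
            class = "cv_report")
}

#' Repeated random sub-sampling cross-validation
#'
#' Uniform cow-level partition into training and testing sets (716/250 at
#' the full cohort scale), repeated `repeats` times; each repeat fits every
#' requested method x model combination and records predictive R-squared
#' and dispersion slope on the test set.
#'
#' @param bundle a [cow_bundle()].
#' @param traits trait names (default: all).
#' @param methods subset of `c("kernel", "bayesb", "pls")`.
#' @param models subset of `"M1"`..`"M7"`; combinations outside a method's
#'   catalogue are skipped for that method.
#' @param n_test test-set size per repeat.
#' @param repeats number of repeats (default 10).
#' @param seed master seed; per-repeat seeds are spawned from it.
#' @param mcmc,prior sampler settings for the Bayesian methods.
#' @param standardize_scope `"train"` (default) or `"full"` statistics for
#'   spectra/SNP standardization.
#' @param max_components,inner_folds PLS settings.
#' @return object of class `cv_report` with a tidy `results` data frame
#'   (trait, method, model, rep, r2, slope).
#' @export
random_subsampling_cv <- function(bundle,
                                  traits = colnames(bundle$traits),
                                  methods = "kernel",
                                  models = paste0("M", 1:7),
                                  n_test = 250, repeats = 10, seed = 1L,
                                  mcmc = mcmc_control(),
                                  prior = kernel_prior(),
                                  standardize_scope = "train",
                                  max_components = 50, inner_folds = 10) {
  n <- length(bundle$cow_ids)
  if (n_test >= n) stop("n_test must be smaller than the number of cows")
  split_fun <- function(s) {
    idx <- withr::with_seed(s, sample.int(n, n_test))
    list(train = setdiff(seq_len(n), idx), test = sort(idx))
  }
  cv_engine(bundle, "random", split_fun, traits, methods, models, repeats,
            seed, drop_herd = FALSE, mcmc, prior, standardize_scope,
            max_components, inner_folds)
}

#' Herd-blocked cross-validation
#'
#' Herds (not cows) are sampled into training and testing sets, so no herd
#' contributes to both. The herd effect is stripped from every model's
#' fixed effects, and the herd+spectra model (M2) is not admissible under
#' this scheme.
#'
#' @inheritParams random_subsampling_cv
#' @param n_train_herds,n_test_herds herds assigned to each set (65/20 at
#'   the full cohort scale).
#' @return object of class `cv_report`.
#' @export
herd_cv <- function(bundle,
                    traits = colnames(bundle$traits),
                    methods = "kernel",
                    models = setdiff(paste0("M", 1:7), "M2"),
                    n_train_herds = 65, n_test_herds = 20,
                    repeats = 10, seed = 1L,
                    mcmc = mcmc_control(),
                    prior = kernel_prior(),
                    standardize_scope = "train",
                    max_components = 50, inner_folds = 10) {
  if ("M2" %in% models)
    stop("M2 (herd + spectra) is not in the herd cross-validation catalogue")
  herds <- sort(unique(as.character(bundle$onfarm$herd)))
  if (length(herds) < n_train_herds + n_test_herds)
    stop("not enough herds: need ", n_train_herds + n_test_herds,
         ", have ", length(herds))
  hvec <- as.character(bundle$onfarm$herd)
  split_fun <- function(s) {
    picked <- withr::with_seed(s,
      sample(herds, n_train_herds + n_test_herds))
    trn_h <- picked[seq_len(n_train_herds)]
    tst_h <- picked[n_train_herds + seq_len(n_test_herds)]
    stopifnot(length(intersect(trn_h, tst_h)) == 0)
    list(train = which(hvec %in% trn_h), test = which(hvec %in% tst_h))
  }
  cv_engine(bundle, "herd", split_fun, traits, methods, models, repeats,
            seed, drop_herd = TRUE, mcmc, prior, standardize_scope,
            max_components, inner_folds)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report:%s> %d repeat(s), %d trait(s)\n", x$scheme,
              x$repeats, length(x$traits)))
  print(summarize_cv(x))
  invisible(x)
}

#' Aggregate a cross-validation report
#'
#' Mean and standard deviation over repeats of per-repeat R-squared and
#' slope (metrics are averaged per repeat, never pooled across repeats).
#'
#' @param report a `cv_report`.
#' @return data frame: trait, method, model, mean/sd of r2 and slope.
#' @export
summarize_cv <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  r <- report$results
  agg <- stats::aggregate(cbind(r2, slope) ~ trait + method + model, data = r,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)),
                          na.action = stats::na.omit)
  out <- data.frame(trait = agg$trait, method = agg$method, model = agg$model,
                    r2_mean = agg$r2[, "mean"], r2_sd = agg$r2[, "sd"],
                    slope_mean = agg$slope[, "mean"],
                    slope_sd = agg$slope[, "sd"],
                    stringsAsFactors = FALSE)
  out[order(out$trait, out$method, out$model), ]
}
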