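#' MCMC settings
#'
#' Defaults follow the long-chain analysis protocol (50,000 burn-in,
#' 50,000 kept samples, thinning 10). Cross-validation and tests use much
#' shorter chains via this constructor.
#'
#' @param burnin discarded iterations.
#' @param ndraws post-burn-in iterations (running means use all of them;
#'   thinning applies only to stored chains).
#' @param thin storage thinning interval.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(burnin = 50000, ndraws = 50000, thin = 10) {
  stopifnot(burnin >= 0, ndraws >= thin, thin >= 1)
  structure(list(burnin = as.integer(burnin), ndraws = as.integer(ndraws),
                 thin = as.integer(thin)), class = "mcmc_control")
}

#' Variance-component prior for the kernel model
#'
#' Scaled-inverse-chi-square priors with df = 5. Scales follow the default
#' partition rule: a prior proportion `R2` of var(y) is split equally
#' across the random kernel terms (each scale set so the prior mode of the
#' contributed variance, sigma2_k * mean diag K_k, equals its share), and
#' the residual prior mode is var(y) * (1 - R2).
#'
#' @param df,df_e degrees of freedom for kernel and residual variances.
#' @param R2 prior proportion of variance attributed to the random terms.
#' @return list of class `kernel_prior`.
#' @export
kernel_prior <- function(df = 5, df_e = 5, R2 = 0.5) {
  stopifnot(df > 0, df_e > 0, R2 > 0, R2 < 1)
  structure(list(df = df, df_e = df_e, R2 = R2), class = "kernel_prior")
}

# Eigendecomposition of a kernel with PSD check; negative eigenvalues more
# negative than -1e-8 * max are an error, small negatives are clamped to 0.
kernel_eigen <- function(K, label = "kernel") {
  K <- if (inherits(K, "relationship_matrix")) K$values else as.matrix(K)
  e <- eigen(K, symmetric = TRUE)
  dmax <- max(e$values, 0)
  if (min(e$values) < -1e-8 * max(dmax, 1))
    stop(label, " is not positive semidefinite (eigenvalue ",
         format(min(e$values)), ")")
  e$values[e$values < 0] <- 0
  e
}

# simple batch-means Monte Carlo standard error for a chain
mcmc_se <- function(x, nbatch = 20) {
  nb <- min(nbatch, max(2, floor(length(x) / 5)))
  bs <- floor(length(x) / nb)
  bm <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
               numeric(1))
  stats::sd(bm) / sqrt(nb)
}

# crude effective sample size from lag-1 autocorrelation of stored draws
ess_lag1 <- function(x) {
  if (length(x) < 10 || stats::sd(x) == 0) return(length(x))
  r1 <- stats::cor(x[-1], x[-length(x)])
  r1 <- min(max(r1, 0), 0.999)
  length(x) * (1 - r1) / (1 + r1)
}

#' Fit a Bayesian mixed model with kernel-structured random effects
#'
#' Gibbs sampler for y = X b + sum_k u_k + e with u_k ~ N(0, K_k sigma2_k)
#' and e ~ N(0, I sigma2_e). Fixed effects have a flat prior; each kernel
#' random vector is sampled from its multivariate normal full conditional
#' via the kernel eigendecomposition (independent regressions on
#' eigenvectors scaled by eigenvalues); variances from scaled-inverse
#' chi-square full conditionals. Deterministic given `seed`.
#'
#' @param y numeric phenotype vector (training rows).
#' @param X fixed-effect design matrix (at least an intercept).
#' @param kernels named list of [relationship_matrix()] (or plain matrices)
#'   over the training rows; one or two entries in typical use.
#' @param prior a [kernel_prior()].
#' @param mcmc an [mcmc_control()].
#' @param seed integer seed.
#' @param fixed_variances optional named list to clamp variances instead of
#'   sampling them: elements named after kernels plus optionally `e`.
#' @param eigen_cache optional named list of precomputed `eigen()` results
#'   per kernel (as from [kernel_eigen()]), to share across model fits.
#' @param store_effects store thinned chains of the random effects (memory
#'   permitting); needed for Monte Carlo standard errors of u.
#' @return object of class `kernel_fit`: posterior means `b_hat`, `u_hat`
#'   (list per kernel), `varcomp`, stored `chains`, and `mcmc_meta`.
#' @export
fit_kernel_model <- function(y, X, kernels,
                             prior = kernel_prior(),
                             mcmc = mcmc_control(),
                             seed = 1L,
                             fixed_variances = NULL,
                             eigen_cache = NULL,
                             store_effects = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("training phenotypes must be complete")
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X row count mismatch")
  # drop aliased columns so X'X is invertible
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping ", ncol(X) - qrX$rank, " aliased fixed-effect column(s)")
    X <- X[, sort(keep), drop = FALSE]
  }
  if (is.null(names(kernels)))
    names(kernels) <- paste0("K", seq_along(kernels))
  K <- length(kernels)
  vy <- stats::var(y)
  if (vy == 0) stop("phenotype has zero variance")

  eig <- vector("list", K)
  Su <- df_u <- s2u0 <- numeric(K)
  fixu <- logical(K)
  for (k in seq_len(K)) {
    nm <- names(kernels)[k]
    Kk <- kernels[[k]]
    Kv <- if (inherits(Kk, "relationship_matrix")) Kk$values else as.matrix(Kk)
    if (nrow(Kv) != n) stop("kernel '", nm, "' dimension mismatch")
    eig[[k]] <- if (!is.null(eigen_cache[[nm]])) eigen_cache[[nm]]
                else kernel_eigen(Kv, nm)
    mdiag <- mean(diag(Kv))
    share <- prior$R2 / K
    # prior mode of sigma2_k set to var(y)*share / mean diag
    Su[k] <- vy * share * (prior$df + 2) / max(mdiag, 1e-8)
    df_u[k] <- prior$df
    if (!is.null(fixed_variances[[nm]])) {
      fixu[k] <- TRUE
      s2u0[k] <- fixed_variances[[nm]]
    } else {
      s2u0[k] <- vy * share / max(mdiag, 1e-8)
    }
  }
  Se <- vy * (1 - prior$R2) * (prior$df_e + 2)
  fixe <- !is.null(fixed_variances[["e"]])
  s2e0 <- if (fixe) fixed_variances[["e"]] else vy * (1 - prior$R2)

  res <- withr::with_seed(seed, {
    kernel_mcmc_cpp(y, X,
                    lapply(eig, `[[`, "vectors"),
                    lapply(eig, `[[`, "values"),
                    df_u, Su, prior$df_e, Se,
                    s2u0, fixu, s2e0, fixe,
                    mcmc$burnin, mcmc$ndraws, mcmc$thin,
                    store_effects)
  })

  chains <- list(sigma2 = res$chain_var, b = res$chain_b)
  colnames(chains$sigma2) <- c(names(kernels), "e")
  colnames(chains$b) <- colnames(X)
  if (store_effects) {
    chains$u <- res$chain_u
    names(chains$u) <- names(kernels)
  }
  ess <- apply(chains$sigma2, 2, ess_lag1)
  if (any(ess < 50))
    warning("low effective sample size for variance component(s): ",
            paste(names(ess)[ess < 50], collapse = ", "))
  u_hat <- res$u_mean
  names(u_hat) <- names(kernels)
  varcomp <- c(stats::setNames(as.numeric(res$sigma2_u_mean),
                               paste0("sigma2_", names(kernels))),
               sigma2_e = res$sigma2_e_mean)
  fitted <- as.numeric(X %*% res$b_mean) + Reduce(`+`, u_hat)
  structure(list(b_hat = stats::setNames(as.numeric(res$b_mean), colnames(X)),
                 u_hat = u_hat,
                 varcomp = varcomp,
                 chains = chains,
                 fitted = fitted,
                 X_names = colnames(X),
                 kernel_names = names(kernels),
                 y = y,
                 mcmc_meta = list(burnin = mcmc$burnin, ndraws = mcmc$ndraws,
                                  thin = mcmc$thin, seed = seed,
                                  ess = ess)),
            class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("<kernel_fit>", length(x$y), "records;",
      length(x$kernel_names), "kernel term(s):",
      paste(x$kernel_names, collapse = ", "), "\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

# solve K_trn,trn x = u with a one-shot 1e-8 diagonal jitter fallback
solve_kernel_train <- function(Ktrn, u, label = "kernel") {
  out <- tryCatch(solve(Ktrn, u), error = function(e) NULL)
  if (is.null(out)) {
    message("singular ", label, " training block; adding 1e-8 jitter")
    out <- tryCatch(solve(Ktrn + diag(1e-8, nrow(Ktrn)), u),
                    error = function(e)
                      stop("singular ", label,
                           " training block even after jitter"))
  }
  out
}

#' Predict test-set phenotypes from a kernel-model fit
#'
#' Conditional-expectation prediction: for each kernel term,
#' K_tst,trn K_trn,trn^-1 u_hat, plus X_tst b_hat for models that include
#' fixed effects (all but M1). Test herds unseen in training carry zero
#' (reference-centered) herd effect by design of the one-hot coding.
#'
#' @param fit a `kernel_fit`.
#' @param kernels_full named list of [relationship_matrix()] (or matrices)
#'   spanning training + test rows; names must match the fit's kernels.
#' @param train_idx,test_idx row indices into the full kernels.
#' @param X_tst fixed-effect design for the test rows (columns as in the
#'   fit); ignored when `include_fixed = FALSE`.
#' @param include_fixed include the X_tst b_hat term (FALSE reproduces the
#'   spectra-only model's prediction, which has no fixed-effect part).
#' @return numeric vector of predictions for the test rows.
#' @export
predict_kernel_testset <- function(fit, kernels_full, train_idx, test_idx,
                                   X_tst = NULL, include_fixed = TRUE) {
  stopifnot(inherits(fit, "kernel_fit"))
  pred <- numeric(length(test_idx))
  if (include_fixed) {
    if (is.null(X_tst)) stop("X_tst required when fixed effects are included")
    X_tst <- as.matrix(X_tst)
    if (!all(fit$X_names %in% colnames(X_tst)))
      stop("X_tst lacks fitted fixed-effect columns")
    X_tst <- X_tst[, fit$X_names, drop = FALSE]
    pred <- as.numeric(X_tst %*% fit$b_hat)
  }
  for (nm in fit$kernel_names) {
    Kf <- kernels_full[[nm]]
    if (is.null(Kf)) stop("kernel '", nm, "' missing from kernels_full")
    Kv <- if (inherits(Kf, "relationship_matrix")) Kf$values else as.matrix(Kf)
    Ktrn <- Kv[train_idx, train_idx, drop = FALSE]
    Ktst <- Kv[test_idx, train_idx, drop = FALSE]
    pred <- pred + as.numeric(Ktst %*% solve_kernel_train(Ktrn, fit$u_hat[[nm]], nm))
  }
  pred
}

#' Back-solve per-SNP effects from a genomic kernel fit
#'
#' Standard GBLUP back-solution consistent with VanRaden scaling:
#' a_hat = Z' G^-1 u_g / (2 sum p_j (1 - p_j)), using the allele
#' frequencies and denominator stored in the kernel's metadata.
#'
#' @param fit a `kernel_fit` containing a genomic term.
#' @param G the `"genomic"` [relationship_matrix()] restricted to the
#'   training rows used by the fit (must carry construction metadata).
#' @param g the [genotype_matrix()] (full panel); training rows are taken
#'   by the kernel's ids.
#' @param kernel_name name of the genomic term in the fit (default "G").
#' @return named numeric vector of marker effect estimates.
#' @export
backsolve_snp_effects <- function(fit, G, g, kernel_name = "G") {
  stopifnot(inherits(fit, "kernel_fit"))
  if (!kernel_name %in% fit$kernel_names)
    stop("fit has no kernel term named '", kernel_name, "'")
  if (!inherits(G, "relationship_matrix") || G$kind != "genomic" ||
      is.null(G$meta$denom) || is.null(G$meta$p))
    stop("G was not built by genomic_kernel(): unknown scaling")
  u <- fit$u_hat[[kernel_name]]
  if (length(u) != nrow(G$values)) stop("G does not match the training rows")
  d <- g$dosages[match(G$ids, g$cow_ids), G$meta$snp_ids, drop = FALSE]
  if (anyNA(d)) stop("genotypes must be imputed")
  Z <- sweep(d, 2, 2 * G$meta$p, "-")
  a <- crossprod(Z, solve_kernel_train(G$values, u, "G")) / G$meta$denom
  stats::setNames(as.numeric(a), G$meta$snp_ids)
}
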