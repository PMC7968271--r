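#' Moments of the Beta hyper-prior on the inclusion probability
#'
#' The mixture-prior inclusion probability pi receives a Beta prior
#' parameterised by its prior mean `prob_in` and concentration `counts`
#' (shape1 = prob_in * counts, shape2 = (1 - prob_in) * counts). The prior
#' variance is prob_in (1 - prob_in) / (counts + 1).
#'
#' @param prob_in prior mean of pi, in (0, 1).
#' @param counts prior concentration, > 0.
#' @return named numeric vector `c(variance, mean)`.
#' @examples
#' beta_prior_moments(0.5, 10)  # variance 0.023 (3 dp), mean 0.5
#' @export
beta_prior_moments <- function(prob_in, counts) {
  if (!is.numeric(prob_in) || prob_in <= 0 || prob_in >= 1)
    stop("prob_in must be in (0, 1)")
  if (!is.numeric(counts) || counts <= 0)
    stop("counts must be > 0")
  c(variance = prob_in * (1 - prob_in) / (counts + 1), mean = prob_in)
}

#' Mixture prior for one predictor layer
#'
#' Point mass at zero plus a scaled-t slab (implemented hierarchically as a
#' normal with scaled-inverse-chi-square variance). The inclusion
#' probability pi is either Beta-updated (default, prob_in = 0.5,
#' counts = 10) or fixed.
#'
#' @param probin prior mean of pi.
#' @param counts Beta concentration.
#' @param df scaled-t degrees of freedom.
#' @param scale scaled-t scale (trait-variance units); when `NULL` it is
#'   filled in by [default_hyperparameters()].
#' @param pi_fixed when non-`NULL`, pi is clamped to this value and not
#'   updated.
#' @return list of class `mixture_prior`.
#' @export
mixture_prior <- function(probin = 0.5, counts = 10, df = 5, scale = NULL,
                          pi_fixed = NULL) {
  stopifnot(probin > 0, probin <= 1, counts > 0, df > 0)
  if (!is.null(pi_fixed)) stopifnot(pi_fixed > 0, pi_fixed <= 1)
  structure(list(probin = probin, counts = counts, df = df, scale = scale,
                 pi_fixed = pi_fixed), class = "mixture_prior")
}

#' One predictor layer for (multilayer) BayesB
#'
#' @param design standardized predictor matrix (wavenumbers or SNP dosages),
#'   columns named.
#' @param label layer label, e.g. `"IR"` or `"SNP"`, unique within a model.
#' @param prior a [mixture_prior()].
#' @return list of class `layer_spec`.
#' @export
layer_spec <- function(design, label, prior = mixture_prior()) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0(label, seq_len(ncol(design)))
  structure(list(design = design, label = label, prior = prior),
            class = "layer_spec")
}

#' Default hyperparameters for BayesB layers and the residual
#'
#' The total prior R-squared is split equally across layers. Each layer's
#' t-scale is chosen so the prior expected variance contributed by the
#' layer, pi0 * sum(column variances) * E[effect variance], equals its
#' share of var(y) * R2_total (E[sigma2] = df * scale / (df - 2)); the
#' residual scale sets the prior mode to var(y) * (1 - R2_total).
#'
#' @param y phenotype vector.
#' @param layers list of [layer_spec()].
#' @param R2_total prior proportion of variance from the layers.
#' @param df_e residual degrees of freedom.
#' @return list: `layers` (each with `df`, `scale`, `Ssum`), `df_e`, `Se`
#'   (residual sum-scale), `var_y`.
#' @export
default_hyperparameters <- function(y, layers, R2_total = 0.5, df_e = 5) {
  vy <- stats::var(as.numeric(y))
  if (is.na(vy) || vy == 0) stop("phenotype has zero variance")
  L <- length(layers)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    lay <- layers[[l]]
    pr <- lay$prior
    msx <- sum(apply(lay$design, 2, stats::var))
    pi0 <- if (!is.null(pr$pi_fixed)) pr$pi_fixed else pr$probin
    share <- vy * R2_total / L
    if (!is.null(pr$scale)) {
      scale <- pr$scale
    } else {
      # E[sigma2_effect] = df*scale/(df-2); pi0 * msx * E = share
      scale <- share * (pr$df - 2) / (pr$df * pi0 * max(msx, 1e-12))
    }
    out[[l]] <- list(label = lay$label, df = pr$df, scale = scale,
                     Ssum = pr$df * scale)
  }
  list(layers = out, df_e = df_e, Se = vy * (1 - R2_total) * (df_e + 2),
       var_y = vy)
}

fit_bayesb_core <- function(y, layers, X, mcmc, seed, R2_total = 0.5,
                            df_e = 5, var_b = 1e8, fixed_sigma2_e = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("at least 10 records are required")
  if (stats::sd(y) == 0) stop("phenotype is constant")
  # a layer with no informative column contributes nothing: drop it so the
  # fit reduces exactly to the remaining layers
  keep <- vapply(layers, function(l) {
    ncol(l$design) > 0 && any(colSums(l$design^2) > 1e-12)
  }, logical(1))
  if (!all(keep)) {
    message("dropping ", sum(!keep), " empty predictor layer(s)")
    layers <- layers[keep]
  }
  if (!length(layers)) stop("no informative predictor layers")
  labs <- vapply(layers, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("layer labels must be unique")
  cols <- unlist(lapply(layers, function(l) colnames(l$design)))
  if (anyDuplicated(cols))
    stop("duplicated column labels across layers")
  for (l in layers) if (nrow(l$design) != n)
    stop("layer '", l$label, "' row count mismatch")
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X row count mismatch")

  hyp <- default_hyperparameters(y, layers, R2_total = R2_total, df_e = df_e)
  L <- length(layers)
  df_a <- vapply(hyp$layers, `[[`, numeric(1), "df")
  Sa <- vapply(hyp$layers, `[[`, numeric(1), "Ssum")
  pi_init <- pi_upd <- numeric(L)
  b1 <- b2 <- numeric(L)
  for (l in seq_len(L)) {
    pr <- layers[[l]]$prior
    if (!is.null(pr$pi_fixed)) {
      pi_init[l] <- pr$pi_fixed; pi_upd[l] <- 0
      b1[l] <- 1; b2[l] <- 1
    } else {
      pi_init[l] <- pr$probin; pi_upd[l] <- 1
      b1[l] <- pr$probin * pr$counts
      b2[l] <- (1 - pr$probin) * pr$counts
    }
  }
  fixe <- !is.null(fixed_sigma2_e)
  s2e0 <- if (fixe) fixed_sigma2_e else hyp$var_y * 0.5

  res <- withr::with_seed(seed, {
    bayesb_mcmc_cpp(y, X, lapply(layers, `[[`, "design"),
                    df_a, Sa, pi_init, as.logical(pi_upd), b1, b2,
                    hyp$df_e, hyp$Se, s2e0, fixe, var_b,
                    mcmc$burnin, mcmc$ndraws, mcmc$thin)
  })

  a_hat <- pip <- list()
  for (l in seq_len(L)) {
    a_hat[[labs[l]]] <- stats::setNames(as.numeric(res$a_mean[[l]]),
                                        colnames(layers[[l]]$design))
    pip[[labs[l]]] <- stats::setNames(as.numeric(res$pip[[l]]),
                                      colnames(layers[[l]]$design))
  }
  chain <- res$chain_misc
  colnames(chain) <- c(paste0("pi_", labs), "sigma2_e")
  fitted <- as.numeric(X %*% res$b_mean)
  for (l in seq_len(L))
    fitted <- fitted + as.numeric(layers[[l]]$design %*% res$a_mean[[l]])
  structure(list(b_hat = stats::setNames(as.numeric(res$b_mean), colnames(X)),
                 a_hat = a_hat, pip = pip,
                 pi_mean = stats::setNames(as.numeric(res$pi_mean), labs),
                 sigma2_e = res$sigma2_e_mean,
                 chains = chain,
                 fitted = fitted,
                 layer_labels = labs,
                 layer_cols = lapply(layers, function(l) colnames(l$design)),
                 X_names = colnames(X),
                 hyper = hyp,
                 y = y,
                 mcmc_meta = list(burnin = mcmc$burnin, ndraws = mcmc$ndraws,
                                  thin = mcmc$thin, seed = seed)),
            class = "bayesb_fit")
}

#' Fit BayesB on a single predictor layer (spectra)
#'
#' Effect-wise Gibbs sampling with per-effect inclusion indicators and
#' per-effect variances (the marginal slab is scaled-t); pi is updated from
#' its Beta full conditional unless fixed. Fixed effects receive a Gaussian
#' prior with variance 1e8. Deterministic given `seed`.
#'
#' @param y phenotype vector.
#' @param layer a [layer_spec()] holding the standardized spectra design.
#' @param X fixed-effect design (at least an intercept column).
#' @param mcmc an [mcmc_control()].
#' @param seed integer seed.
#' @param R2_total prior R-squared used by [default_hyperparameters()].
#' @param fixed_sigma2_e optional value clamping the residual variance.
#' @return object of class `bayesb_fit`.
#' @export
fit_bayesb <- function(y, layer, X = matrix(1, length(y), 1,
                                            dimnames = list(NULL, "intercept")),
                       mcmc = mcmc_control(), seed = 1L, R2_total = 0.5,
                       fixed_sigma2_e = NULL) {
  fit_bayesb_core(y, list(layer), X, mcmc, seed, R2_total = R2_total,
                  fixed_sigma2_e = fixed_sigma2_e)
}

#' Fit multilayer BayesB (spectra + SNP layers)
#'
#' As [fit_bayesb()], but both layers are cycled each iteration, each with
#' its own mixture prior (pi, df, scale). By default both layers use a
#' Beta(pi) prior with prob_in = 0.5 and counts = 10.
#'
#' @inheritParams fit_bayesb
#' @param ir_layer,snp_layer [layer_spec()] objects on the same cows.
#' @return object of class `bayesb_fit` with per-layer posterior summaries.
#' @export
fit_multilayer_bayesb <- function(y, ir_layer, snp_layer,
                                  X = matrix(1, length(y), 1,
                                             dimnames = list(NULL, "intercept")),
                                  mcmc = mcmc_control(), seed = 1L,
                                  R2_total = 0.5, fixed_sigma2_e = NULL) {
  fit_bayesb_core(y, list(ir_layer, snp_layer), X, mcmc, seed,
                  R2_total = R2_total, fixed_sigma2_e = fixed_sigma2_e)
}

#' @export
print.bayesb_fit <- function(x, ...) {
  cat("<bayesb_fit>", length(x$y), "records; layers:",
      paste(x$layer_labels, collapse = ", "),
      sprintf("; sigma2_e = %.4f\n", x$sigma2_e))
  invisible(x)
}

#' Predict test-set phenotypes from a BayesB fit
#'
#' Linear combinations per the model catalogue: the spectra-only model uses
#' W_IR,tst a_IR alone; models with on-farm covariates add X_tst b; the
#' two-layer model adds W_SNP,tst a_SNP. Test designs must be standardized
#' with training statistics; no recalibration is applied.
#'
#' @param fit a `bayesb_fit`.
#' @param X_tst test fixed-effect design (ignored if `include_fixed = FALSE`).
#' @param layer_designs named list (by layer label) of test design matrices.
#' @param include_fixed whether the X_tst b term enters the prediction.
#' @return numeric prediction vector.
#' @export
predict_bayesb <- function(fit, X_tst = NULL, layer_designs,
                           include_fixed = TRUE) {
  stopifnot(inherits(fit, "bayesb_fit"))
  ntst <- nrow(as.matrix(layer_designs[[1]]))
  pred <- numeric(ntst)
  if (include_fixed) {
    if (is.null(X_tst)) stop("X_tst required when fixed effects are included")
    X_tst <- as.matrix(X_tst)
    if (!all(fit$X_names %in% colnames(X_tst)))
      stop("X_tst lacks fitted fixed-effect columns")
    pred <- as.numeric(X_tst[, fit$X_names, drop = FALSE] %*% fit$b_hat)
  }
  for (lab in names(layer_designs)) {
    if (!lab %in% fit$layer_labels) stop("unknown layer '", lab, "'")
    W <- as.matrix(layer_designs[[lab]])
    a <- fit$a_hat[[lab]]
    if (ncol(W) != length(a))
      stop("layer '", lab, "' width mismatch with training design")
    pred <- pred + as.numeric(W %*% a)
  }
  pred
}
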