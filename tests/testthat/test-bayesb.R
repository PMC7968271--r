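test_that("Beta-prior moments follow the stated closed form", {
  m <- beta_prior_moments(0.5, 10)
  expect_equal(round(m[["variance"]], 3), 0.023)
  expect_equal(m[["mean"]], 0.5)
  # concentration limit: variance -> 0
  expect_lt(beta_prior_moments(0.5, 1e9)[["variance"]], 1e-9)
  # direct evaluation at another point
  expect_equal(beta_prior_moments(0.2, 4)[["variance"]], 0.032)
  expect_equal(beta_prior_moments(0.2, 4)[["mean"]], 0.2)
  expect_error(beta_prior_moments(0, 10), "prob_in")
  expect_error(beta_prior_moments(0.5, -1), "counts")
})

test_that("default hyperparameters split the variance budget and scale with
           the phenotype", {
  withr::with_seed(13, {
    y <- rnorm(50, 0, 2)
    W1 <- scale(matrix(rnorm(50 * 20), 50, 20))
    W2 <- scale(matrix(rnorm(50 * 20), 50, 20))
    colnames(W1) <- paste0("a", 1:20); colnames(W2) <- paste0("b", 1:20)
  })
  l1 <- layer_spec(W1, "IR"); l2 <- layer_spec(W2, "SNP")
  h <- default_hyperparameters(y, list(l1, l2), R2_total = 0.5)
  # equal widths -> equal per-layer budget
  expect_equal(h$layers[[1]]$scale, h$layers[[2]]$scale, tolerance = 1e-6)
  # residual prior mode = (1 - R2) var(y)
  expect_equal(h$Se / (h$df_e + 2), 0.5 * var(y), tolerance = 1e-12)
  h1 <- default_hyperparameters(y, list(l1), R2_total = 0.5)
  expect_equal(h1$Se / (h1$df_e + 2), 0.5 * var(y))
  # doubling the phenotype scale quadruples variances -> scales all scales
  h2 <- default_hyperparameters(2 * y, list(l1, l2), R2_total = 0.5)
  expect_equal(h2$layers[[1]]$scale / h$layers[[1]]$scale, 4,
               tolerance = 1e-10)
  expect_equal(h2$Se / h$Se, 4, tolerance = 1e-10)
})

test_that("BayesB is deterministic given the seed and shrinks null effects
           with sample size", {
  make_null <- function(n, seed) {
    withr::with_seed(seed, {
      W <- scale(matrix(rnorm(n * 40), n, 40))
      colnames(W) <- paste0("w", 1:40)
      list(W = W, y = rnorm(n))
    })
  }
  d <- make_null(60, 17)
  mc <- mcmc_control(400, 800, 4)
  f1 <- fit_bayesb(d$y, layer_spec(d$W, "IR"), mcmc = mc, seed = 3)
  f2 <- fit_bayesb(d$y, layer_spec(d$W, "IR"), mcmc = mc, seed = 3)
  expect_identical(f1$a_hat, f2$a_hat)
  expect_identical(f1$sigma2_e, f2$sigma2_e)
  expect_true(all(f1$pip$IR >= 0 & f1$pip$IR <= 1))

  # mean |effect| halves from n = 50 to n = 400 on pure noise
  small <- make_null(50, 18); big <- make_null(400, 19)
  fs <- fit_bayesb(small$y, layer_spec(small$W, "IR"), mcmc = mc, seed = 4)
  fb <- fit_bayesb(big$y, layer_spec(big$W, "IR"), mcmc = mc, seed = 4)
  expect_lt(mean(abs(fb$a_hat$IR)), 0.5 * mean(abs(fs$a_hat$IR)))

  # null-simulation inclusion probabilities stay near the prior mean
  expect_lt(abs(mean(fs$pip$IR) - 0.5), 0.15)

  expect_error(fit_bayesb(rep(1, 20),
                          layer_spec(scale(matrix(rnorm(20 * 5), 20, 5)),
                                     "IR")),
               "constant")
})

test_that("an all-zero SNP layer reduces the multilayer fit to spectra-only", {
  withr::with_seed(23, {
    n <- 40
    W <- scale(matrix(rnorm(n * 25), n, 25)); colnames(W) <- paste0("w", 1:25)
    y <- W[, 1] * 0.5 + rnorm(n)
  })
  Z0 <- matrix(0, n, 10); colnames(Z0) <- paste0("z", 1:10)
  mc <- mcmc_control(300, 600, 3)
  f_single <- fit_bayesb(y, layer_spec(W, "IR"), mcmc = mc, seed = 5)
  expect_message(
    f_multi <- fit_multilayer_bayesb(y, layer_spec(W, "IR"),
                                     layer_spec(Z0, "SNP"),
                                     mcmc = mc, seed = 5),
    "empty predictor layer")
  expect_identical(f_multi$a_hat$IR, f_single$a_hat$IR)
  expect_identical(f_multi$sigma2_e, f_single$sigma2_e)

  # duplicated column labels across layers are rejected
  Wd <- W; colnames(Wd) <- paste0("w", 1:25)
  expect_error(fit_multilayer_bayesb(y, layer_spec(W, "IR"),
                                     layer_spec(Wd[, 1:3], "SNP"),
                                     mcmc = mc, seed = 5),
               "duplicated column labels")
})

test_that("two informative layers fit the training data better than the
           spectra layer alone when genetic signal exists", {
  sim <- desk_sim(seed = 24, n_cows = 150, n_herds = 13, m_snp = 120,
                  m_ir = 60, missing_rate = 0, qtl_share = 0.8,
                  herd_share = 0, dim_share = 0, parity_share = 0)
  b <- sim$bundle
  y <- b$traits[, "kappa_CN"]
  Wir <- standardize_columns(b$spectra$values)$values
  Wsnp <- standardize_columns(b$genotypes$dosages)$values
  mc <- mcmc_control(500, 1000, 5)
  f1 <- fit_bayesb(y, layer_spec(Wir, "IR"), mcmc = mc, seed = 6)
  f2 <- fit_multilayer_bayesb(y, layer_spec(Wir, "IR"),
                              layer_spec(Wsnp, "SNP"), mcmc = mc, seed = 6)
  expect_gt(cor(f2$fitted, y), cor(f1$fitted, y))
})

test_that("BayesB predictions are the stated linear combinations", {
  withr::with_seed(25, {
    n <- 30
    W <- scale(matrix(rnorm(n * 15), n, 15)); colnames(W) <- paste0("w", 1:15)
    Z <- scale(matrix(rnorm(n * 8), n, 8)); colnames(Z) <- paste0("s", 1:8)
    X <- cbind(intercept = 1, cov = rnorm(n))
    y <- 1 + W[, 2] - Z[, 3] + rnorm(n, 0, 0.5)
  })
  mc <- mcmc_control(300, 600, 3)
  fit <- fit_multilayer_bayesb(y, layer_spec(W, "IR"), layer_spec(Z, "SNP"),
                               X = X, mcmc = mc, seed = 7)
  # a test row equal to a training row reproduces its fitted value
  p <- predict_bayesb(fit, X_tst = X[4, , drop = FALSE],
                      layer_designs = list(IR = W[4, , drop = FALSE],
                                           SNP = Z[4, , drop = FALSE]))
  expect_equal(p, fit$fitted[4], tolerance = 1e-10)
  # dropping the SNP layer changes the prediction by exactly W_snp a_snp
  p_ir <- predict_bayesb(fit, X_tst = X[1:5, ],
                         layer_designs = list(IR = W[1:5, ]))
  p_both <- predict_bayesb(fit, X_tst = X[1:5, ],
                           layer_designs = list(IR = W[1:5, ],
                                                SNP = Z[1:5, ]))
  expect_equal(p_both - p_ir, as.numeric(Z[1:5, ] %*% fit$a_hat$SNP),
               tolerance = 1e-10)
  # zero effects leave only the fixed part
  f0 <- fit
  f0$a_hat$IR[] <- 0; f0$a_hat$SNP[] <- 0
  p0 <- predict_bayesb(f0, X_tst = X[1:5, ],
                       layer_designs = list(IR = W[1:5, ], SNP = Z[1:5, ]))
  expect_equal(p0, as.numeric(X[1:5, ] %*% fit$b_hat), tolerance = 1e-10)
  # width mismatch errors
  expect_error(predict_bayesb(fit, X_tst = X[1:5, ],
                              layer_designs = list(IR = W[1:5, 1:7])),
               "width mismatch")
})

test_that("column permutation permutes posterior summaries up to Monte
           Carlo error, and short chains track long chains", {
  withr::with_seed(26, {
    n <- 100
    W <- scale(matrix(rnorm(n * 60), n, 60)); colnames(W) <- paste0("w", 1:60)
    beta <- numeric(60); beta[c(5, 20)] <- c(0.8, -0.8)
    y <- as.numeric(W %*% beta) + rnorm(n)
  })
  perm <- sample(60)
  Wp <- W[, perm]
  long <- mcmc_control(2000, 6000, 5)
  f <- fit_bayesb(y, layer_spec(W, "IR"), mcmc = long, seed = 8)
  fp <- fit_bayesb(y, layer_spec(Wp, "IR"), mcmc = long, seed = 8)
  # same columns, same names -> summaries agree to MC error after inverting
  # the permutation (the Gibbs scan order differs, so not bitwise)
  expect_gt(cor(f$a_hat$IR[colnames(Wp)], fp$a_hat$IR), 0.99)

  short <- fit_bayesb(y, layer_spec(W, "IR"),
                      mcmc = mcmc_control(2000, 2000, 5), seed = 9)
  expect_gt(cor(short$a_hat$IR, f$a_hat$IR), 0.95)
})
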