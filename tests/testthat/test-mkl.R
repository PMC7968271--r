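test_that("kernel model with vanishing kernel variance reduces to
           fixed-effects least squares", {
  withr::with_seed(1, {
    n <- 40
    X <- cbind(intercept = 1, x = rnorm(n))
    y <- 2 + 0.5 * X[, 2] + rnorm(n, 0, 0.3)
    K <- genomic_kernel(genotype_matrix({
      d <- matrix(rbinom(n * 60, 2, 0.4), n, 60); d
    }))
  })
  fit <- fit_kernel_model(y, X, list(G = K),
                          mcmc = mcmc_control(500, 1500, 5), seed = 2,
                          fixed_variances = list(G = 1e-12, e = 0.09))
  ols <- lm.fit(X, y)
  expect_lt(max(abs(fit$b_hat - ols$coefficients)), 0.05)
  expect_lt(max(abs(fit$u_hat$G)), 1e-4)
})

test_that("same seed gives identical posterior means", {
  sim <- desk_sim(seed = 41, n_cows = 60, n_herds = 6, m_snp = 80, m_ir = 30,
                  missing_rate = 0)
  b <- sim$bundle
  G <- genomic_kernel(b$genotypes)
  y <- b$traits[, "TP"]
  X <- matrix(1, 60, 1, dimnames = list(NULL, "intercept"))
  mc <- mcmc_control(200, 400, 4)
  f1 <- fit_kernel_model(y, X, list(G = G), mcmc = mc, seed = 9)
  f2 <- fit_kernel_model(y, X, list(G = G), mcmc = mc, seed = 9)
  expect_identical(f1$u_hat, f2$u_hat)
  expect_identical(f1$varcomp, f2$varcomp)
})

test_that("residual-variance posterior is positive and bounded on a
           well-posed fit; non-PSD kernels are rejected", {
  sim <- desk_sim(seed = 42, n_cows = 80, n_herds = 8, m_snp = 60, m_ir = 40,
                  missing_rate = 0)
  b <- sim$bundle
  y <- b$traits[, "kappa_CN"]
  st <- standardize_columns(b$spectra$values)
  S <- spectral_kernel(st$values, m_total = 40, ids = b$cow_ids)
  fit <- fit_kernel_model(y, matrix(1, 80, 1, dimnames = list(NULL, "mu")),
                          list(S = S), mcmc = mcmc_control(500, 1000, 5),
                          seed = 3)
  expect_gt(fit$varcomp[["sigma2_e"]], 0)
  expect_lt(fit$varcomp[["sigma2_e"]], 1.5 * var(y))

  bad <- diag(4); bad[1, 1] <- -0.5
  expect_error(
    fit_kernel_model(rnorm(4), matrix(1, 4, 1), list(K = bad),
                     mcmc = mcmc_control(10, 10, 1)),
    "positive semidefinite")
})

test_that("exchanging the order of the two kernels leaves posterior-mean
           predictions unchanged within Monte Carlo error", {
  sim <- desk_sim(seed = 44, n_cows = 70, n_herds = 7, m_snp = 80, m_ir = 120,
                  missing_rate = 0)
  b <- sim$bundle
  trn <- 1:55; tst <- 56:70
  st <- standardize_columns(b$spectra$values, stats_from = trn)
  S <- spectral_kernel(st$values, m_total = 120, ids = b$cow_ids)
  G <- genomic_kernel(b$genotypes)
  y <- b$traits[, "beta_CN"]
  X <- cbind(intercept = rep(1, 70), dim = b$onfarm$dim)
  mc <- mcmc_control(1500, 4000, 5)
  Ktrn1 <- list(S = S$values[trn, trn], G = G$values[trn, trn])
  Ktrn2 <- rev(Ktrn1)
  f1 <- fit_kernel_model(y[trn], X[trn, ], Ktrn1, mcmc = mc, seed = 5)
  f2 <- fit_kernel_model(y[trn], X[trn, ], Ktrn2, mcmc = mc, seed = 50)
  p1 <- predict_kernel_testset(f1, list(S = S, G = G), trn, tst, X[tst, ])
  p2 <- predict_kernel_testset(f2, list(S = S, G = G), trn, tst, X[tst, ])
  expect_lt(sqrt(mean((p1 - p2)^2)), 0.12 * sd(y))
})

test_that("a test cow duplicating a training cow gets that cow's fitted
           value, and model differences are the added kernel term", {
  n <- 16
  w <- rand_spectra(n, 50, seed = 21)
  dup <- 5  # test cow duplicates training cow 5
  w_all <- rbind(w, w[dup, , drop = FALSE])
  rownames(w_all) <- c(rownames(w), "dupcow")
  st <- standardize_columns(w_all, stats_from = 1:n)
  S <- spectral_kernel(st$values, m_total = 50)
  withr::with_seed(6, {
    X_all <- cbind(intercept = 1, dim = c(rnorm(n), 0))
    X_all[n + 1, "dim"] <- X_all[dup, "dim"]
    y <- rnorm(n)
  })
  fit <- fit_kernel_model(y, X_all[1:n, ], list(S = S$values[1:n, 1:n]),
                          mcmc = mcmc_control(300, 600, 3), seed = 7)
  pred <- predict_kernel_testset(fit, list(S = S), 1:n, n + 1,
                                 X_all[n + 1, , drop = FALSE])
  expect_equal(pred, fit$fitted[dup], tolerance = 1e-6)

  # linearity: adding a second kernel term to the prediction formula
  # changes it by exactly that kernel's contribution
  withr::with_seed(8, {
    K2 <- tcrossprod(matrix(rnorm((n + 1) * 30), n + 1, 30)) / 30
    u2 <- rnorm(n)
  })
  f3 <- manual_kernel_fit(fit$b_hat, fit$u_hat, fit$X_names, y)
  f4 <- manual_kernel_fit(fit$b_hat, c(fit$u_hat, list(K2 = u2)),
                          fit$X_names, y)
  p3 <- predict_kernel_testset(f3, list(S = S), 1:n, n + 1,
                               X_all[n + 1, , drop = FALSE])
  p4 <- predict_kernel_testset(f4, list(S = S, K2 = K2), 1:n, n + 1,
                               X_all[n + 1, , drop = FALSE])
  term <- as.numeric(K2[n + 1, 1:n] %*% solve(K2[1:n, 1:n], u2))
  expect_equal(p4 - p3, term, tolerance = 1e-8)
})

test_that("with G = c I the kernel model's conditional-expectation
           prediction matches a ridge oracle at fixed variances", {
  withr::with_seed(9, {
    n <- 24; ntrn <- 18
    X <- cbind(intercept = rep(1, n))
    y <- rnorm(n)
  })
  cI <- diag(2, n)
  s2u <- 0.7; s2e <- 0.5
  trn <- 1:ntrn; tst <- (ntrn + 1):n
  sol <- oracle_mme(y[trn], X[trn, , drop = FALSE], list(cI[trn, trn]),
                    s2u, s2e)
  fit <- manual_kernel_fit(setNames(sol$b, "intercept"),
                           list(G = sol$u[[1]]), "intercept", y[trn])
  pred <- predict_kernel_testset(fit, list(G = cI), trn, tst,
                                 X[tst, , drop = FALSE])
  # ridge oracle: with K = c I the random effect is i.i.d. with variance
  # c * s2u, so u = shrinkage * (y - X b) elementwise
  shrink <- (2 * s2u) / (2 * s2u + s2e)
  u_ridge <- shrink * (y[trn] - as.numeric(X[trn, , drop = FALSE] %*% sol$b))
  expect_equal(sol$u[[1]], u_ridge, tolerance = 1e-6)
  # the off-block of c I is zero: test predictions are X b alone
  expect_equal(pred, as.numeric(X[tst, , drop = FALSE] %*% sol$b),
               tolerance = 1e-6)
})

test_that("SNP effects back-solve from the genomic kernel fit", {
  # u = 0 gives all-zero effects
  withr::with_seed(10, d <- matrix(rbinom(8 * 12, 2, 0.4), 8, 12))
  for (j in 1:12) if (length(unique(d[, j])) == 1) d[1, j] <- (d[1, j] + 1) %% 3
  g <- genotype_matrix(d)
  G <- genomic_kernel(g)
  f0 <- manual_kernel_fit(c(intercept = 0), list(G = rep(0, 8)),
                          "intercept", rnorm(8))
  expect_equal(unname(backsolve_snp_effects(f0, G, g)), rep(0, 12))

  # single-SNP panel: back-solved effect equals the regression of u on the
  # centered SNP (1-SNP closed form)
  g1 <- genotype_matrix(cbind(snpA = d[, 1]))
  G1 <- genomic_kernel(g1)
  z <- d[, 1] - mean(d[, 1])  # centered dosage (2p = mean dosage)
  u <- 0.8 * z  # u in the span of the SNP
  f1 <- manual_kernel_fit(c(intercept = 0), list(G = u), "intercept", u)
  suppressMessages(a1 <- backsolve_snp_effects(f1, G1, g1))
  expect_equal(unname(a1), 0.8, tolerance = 1e-4)

  # unknown scaling is rejected
  Gplain <- relationship_matrix(G$values, "genomic", ids = G$ids)
  expect_error(backsolve_snp_effects(f0, Gplain, g), "unknown scaling")
})
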