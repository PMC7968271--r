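test_that("acquisition averaging is the per-cow arithmetic mean", {
  grid <- c("3000", "2000", "1000")
  one <- matrix(c(0.1, 0.2, 0.3), 1, dimnames = list(NULL, grid))
  raw <- list(cowA = rbind(one, one),
              cowB = matrix(c(0, 2, 2, 2, 0, 0), 2, byrow = TRUE,
                            dimnames = list(NULL, grid)))
  s <- average_acquisitions(raw)
  expect_equal(unname(s$values["cowA", ]), c(0.1, 0.2, 0.3))
  expect_equal(unname(s$values["cowB", ]), c(1, 1, 1))

  # brute-force row-mean oracle on random replicates
  withr::with_seed(42, {
    raw <- lapply(1:5, function(i)
      matrix(rnorm(2 * 3), 2, dimnames = list(NULL, grid)))
    names(raw) <- paste0("c", 1:5)
  })
  s <- average_acquisitions(raw)
  oracle <- t(vapply(raw, function(m)
    vapply(seq_len(ncol(m)), function(j) sum(m[, j]) / nrow(m), numeric(1)),
    numeric(3)))
  expect_equal(unname(s$values), unname(oracle))
})

test_that("acquisition averaging rejects mismatched wavenumber grids", {
  raw <- list(ok = matrix(1, 1, 2, dimnames = list(NULL, c("a", "b"))),
              bad = matrix(1, 1, 2, dimnames = list(NULL, c("a", "c"))))
  expect_error(average_acquisitions(raw), "bad")
})

test_that("genotype QC removes below-threshold SNPs, keeps boundary values", {
  d50 <- cbind(snp1 = c(rep(NA, 3), rep(1, 47)),     # call rate 0.94
               snp2 = c(rep(1, 4), rep(0, 46)),       # freq 4/100 = 0.04
               snp3 = c(rep(1, 5), rep(0, 45)),       # maf exactly 0.05
               snp4 = rep(c(0, 1, 2), length.out = 50))
  qc <- genotype_qc(genotype_matrix(d50))
  expect_equal(qc$report$removed, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(qc$genotypes$snp_ids, c("snp3", "snp4"))
  expect_match(qc$report$reason[1], "call_rate")
  expect_equal(qc$report$reason[2], "maf")

  # a SNP with 9/10 calls (rate 0.90) is removed
  d10 <- cbind(snp1 = c(NA, 1, 0, 1, 2, 0, 1, 2, 0, 1),
               snp4 = rep(c(0, 1, 2), length.out = 10))
  qc10 <- genotype_qc(genotype_matrix(d10))
  expect_true(qc10$report$removed[qc10$report$snp == "snp1"])
})

test_that("genotype QC equals a brute-force per-SNP filter on random panels", {
  withr::with_seed(7, {
    d <- matrix(sample(c(0, 1, 2, NA), 20 * 50, replace = TRUE,
                       prob = c(0.4, 0.3, 0.25, 0.05)), 20, 50)
  })
  g <- genotype_matrix(d)
  qc <- genotype_qc(g)
  keep_oracle <- vapply(seq_len(50), function(j) {
    x <- d[, j]
    cr <- sum(!is.na(x)) / 20
    p <- mean(x, na.rm = TRUE) / 2
    maf <- min(p, 1 - p)
    if (is.nan(maf)) maf <- 0
    cr >= 0.95 && maf >= 0.05
  }, logical(1))
  expect_equal(qc$genotypes$snp_ids, g$snp_ids[keep_oracle])
  # idempotence
  qc2 <- genotype_qc(qc$genotypes)
  expect_equal(qc2$genotypes$dosages, qc$genotypes$dosages)
  # empty panel errors
  expect_error(genotype_qc(genotype_matrix(matrix(c(0, NA, NA, NA), 4, 1))),
               "empty panel")
})

test_that("imputation draws Binomial(2, p_ref) and preserves observed calls", {
  # degenerate p_ref = 1
  g <- genotype_matrix(cbind(snp1 = c(2, 2, 2, NA)))
  expect_equal(impute_genotypes(g, seed = 1)$dosages[4, 1], 2)

  # p_ref = 0.5: mean imputed dosage 1.0 +/- 0.03 over 10,000 draws
  d <- rbind(matrix(1, 2, 1), matrix(NA_real_, 10000, 1))
  gi <- impute_genotypes(genotype_matrix(d), seed = 99)
  expect_lt(abs(mean(gi$dosages[-(1:2), 1]) - 1), 0.03)
  expect_equal(gi$dosages[1:2, 1], c(1, 1), ignore_attr = TRUE)

  # seeded determinism
  withr::with_seed(3, {
    d <- matrix(sample(c(0, 1, 2, NA), 100, TRUE), 10, 10)
  })
  d[1, 1] <- 1  # guarantee no all-missing SNP
  g <- genotype_matrix(d)
  expect_identical(impute_genotypes(g, seed = 5)$dosages,
                   impute_genotypes(g, seed = 5)$dosages)

  # all-missing SNP is an error
  expect_error(impute_genotypes(genotype_matrix(cbind(c(NA, NA, NA))), 1),
               "frequency undefined")
})

test_that("spectral outlier screen flags constructed outliers, calibrates, and
           is invariant to channel order", {
  base <- rand_spectra(30, 12, seed = 5)
  base[1:29, ] <- matrix(rep(base[2, ], 29), 29, byrow = TRUE) +
    matrix(rnorm(29 * 12, 0, 1), 29, 12)
  base[30, ] <- base[2, ] + 10 * apply(base[1:29, ], 2, sd)
  s <- spectra_matrix(base, wavenumbers = as.numeric(colnames(base)))
  flagged <- spectral_outlier_screen(s, n_components = 3,
                                     distance_quantile = 0.99)
  expect_true("cow030" %in% flagged)
  d2 <- attr(flagged, "distance")
  expect_equal(names(which.max(d2)), "cow030")
  expect_lte(length(flagged), 3)  # at most the outlier plus chance flags

  # chi-square calibration: ~1% flagged for homogeneous Gaussian spectra
  rates <- vapply(1:25, function(i) {
    x <- rand_spectra(120, 10, seed = 100 + i)
    sp <- spectra_matrix(x, wavenumbers = as.numeric(colnames(x)))
    length(spectral_outlier_screen(sp, 5, 0.99)) / 120
  }, numeric(1))
  expect_gt(mean(rates), 0.001)
  expect_lt(mean(rates), 0.035)

  # permuting wavenumber columns leaves the flagged set unchanged
  x <- rand_spectra(40, 8, seed = 9)
  perm <- c(3, 1, 8, 2, 7, 4, 6, 5)
  s1 <- spectra_matrix(x, wavenumbers = as.numeric(colnames(x)))
  s2 <- spectra_matrix(x[, perm], wavenumbers = seq_len(8))
  expect_identical(as.character(spectral_outlier_screen(s1, 3, 0.95)),
                   as.character(spectral_outlier_screen(s2, 3, 0.95)))
})

test_that("column standardization: forced values, constant-column policy,
           out-of-sample transform, and round-trip identity", {
  st <- standardize_columns(cbind(a = c(0, 2)))
  expect_equal(unname(st$values[, 1]), c(-1, 1) / sqrt(2))

  expect_warning(st2 <- standardize_columns(cbind(a = c(0, 2, 1),
                                                  b = c(3, 3, 3))),
                 "constant")
  expect_equal(colnames(st2$values), "a")

  # training stats applied to held-out rows do not recenter them
  withr::with_seed(2, x <- matrix(rnorm(40), 10, 4))
  st3 <- standardize_columns(x, stats_from = 1:6)
  test_part <- apply_column_stats(x[7:10, ], st3)
  expect_gt(max(abs(colMeans(test_part))), 1e-3)

  # re-standardizing an already-standardized matrix is the identity
  st_full <- standardize_columns(x)
  st4 <- standardize_columns(st_full$values)
  expect_lt(max(abs(st4$values - st_full$values)), 1e-10)
  expect_lt(max(abs(st4$center)), 1e-10)
  expect_lt(max(abs(st4$scale - 1)), 1e-10)
})

test_that("bundle assembly enforces strict id reconciliation", {
  sim <- desk_sim(seed = 21, n_cows = 40, n_herds = 5, m_snp = 30, m_ir = 20)
  b <- sim$bundle
  expect_s3_class(b, "cow_bundle")
  onfarm_bad <- b$onfarm[-3, ]
  expect_error(cow_bundle(b$spectra, b$genotypes, b$pedigree, onfarm_bad,
                          b$traits),
               "reconciliation")
})

test_that("delimited round trip preserves the bundle", {
  sim <- desk_sim(seed = 22, n_cows = 30, n_herds = 4, m_snp = 25, m_ir = 15)
  dir <- withr::local_tempdir()
  write_bundle(sim, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$spectra$values, sim$bundle$spectra$values,
               tolerance = 1e-12)
  expect_equal(b2$genotypes$dosages, sim$bundle$genotypes$dosages)
  expect_equal(b2$onfarm$herd, sim$bundle$onfarm$herd)
  expect_equal(b2$traits, sim$bundle$traits, tolerance = 1e-12)
})
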