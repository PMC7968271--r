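#' Default trait panel: nine milk protein traits
#'
#' Means and standard deviations (% of total milk N) of the cohort the
#' generator is calibrated to: true protein nitrogen, total casein, total
#' whey protein, four casein fractions and two whey proteins.
#'
#' @return data frame with columns `trait`, `mean`, `sd`.
#' @export
milk_protein_traits <- function() {
  data.frame(
    trait = c("TP", "TCN", "TWP", "kappa_CN", "beta_CN",
              "alphaS1_CN", "alphaS2_CN", "beta_LG", "alpha_LA"),
    mean = c(89.1, 78.0, 11.1, 9.45, 32.3, 25.7, 9.20, 8.68, 2.39),
    sd = c(2.25, 1.23, 1.70, 1.48, 2.45, 1.79, 1.14, 1.56, 0.50),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults emulate the study cohort: 966 cows in 85 herds (11.4 +/- 2.4
#' cows per herd), days in milk 169.8 +/- 101.8, parity 2.4 +/- 1.2, 1060
#' wavenumbers spanning 5011-925 cm^-1, and the nine milk protein traits of
#' [milk_protein_traits()]. The SNP panel defaults to 2,000 markers (the
#' machinery scales to the full 37,519). `desk = TRUE` switches to the
#' reduced profile used by the test suite (300 cows, 500 SNPs, 200
#' channels, 26 herds).
#'
#' Trait variance shares: `h2` (genetic), `herd_share`, `dim_share`,
#' `parity_share`, `milk_share` (a latent milk-composition factor that the
#' spectra measure); the remainder is i.i.d. residual. Shares must sum to
#' at most 1. `spectra_herd_loading` scales herd-specific spectral
#' signature curves: at 0 the spectra carry no herd fingerprint and the
#' herd-CV optimism gap of random cross-validation disappears.
#'
#' @param n_cows,n_herds cohort dimensions.
#' @param cows_per_herd_mean,cows_per_herd_sd herd-size distribution
#'   (rounded normal, truncated at 3).
#' @param dim_mean,dim_sd,parity_mean,parity_sd on-farm covariate moments.
#' @param m_ir,wn_max,wn_min spectral grid.
#' @param m_snp,n_qtl,qtl_share SNP panel size, causal markers, and share
#'   of genetic variance carried by them.
#' @param h2 heritability per trait (recycled over the trait table).
#' @param herd_share,dim_share,parity_share,milk_share trait variance
#'   shares.
#' @param spectra_herd_loading,spectra_genetic_loading,spectra_milk_loading
#'   loadings of the latent factors on the spectra.
#' @param spectra_noise_sd,ar1_rho channel noise level and its AR(1)
#'   correlation across adjacent wavenumbers.
#' @param missing_rate fraction of genotype calls set missing.
#' @param traits trait table as in [milk_protein_traits()].
#' @param n_sires,n_dams founder counts (defaults scale with `n_cows`).
#' @param desk use the reduced desk-scale profile.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cows = 966, n_herds = 85,
                       cows_per_herd_mean = 11.4, cows_per_herd_sd = 2.4,
                       dim_mean = 169.8, dim_sd = 101.8,
                       parity_mean = 2.4, parity_sd = 1.2,
                       m_ir = 1060, wn_max = 5011, wn_min = 925,
                       m_snp = 2000, n_qtl = 3, qtl_share = 0.5,
                       h2 = 0.5, herd_share = 0.20,
                       dim_share = 0.03, parity_share = 0.02,
                       milk_share = 0.10,
                       spectra_herd_loading = 1,
                       spectra_genetic_loading = 0.3,
                       spectra_milk_loading = 0.8,
                       spectra_noise_sd = 1.0, ar1_rho = 0.9,
                       missing_rate = 0.01,
                       traits = milk_protein_traits(),
                       n_sires = NULL, n_dams = NULL,
                       desk = FALSE, seed = 1L) {
  if (desk) {
    if (missing(n_cows)) n_cows <- 300
    if (missing(n_herds)) n_herds <- 26
    if (missing(m_snp)) m_snp <- 500
    if (missing(m_ir)) m_ir <- 200
  }
  h2 <- rep(h2, length.out = nrow(traits))
  shares <- h2 + herd_share + dim_share + parity_share + milk_share
  if (any(c(h2, herd_share, dim_share, parity_share, milk_share) < 0) ||
      any(shares > 1 + 1e-12))
    stop("variance shares must be in [0, 1] and sum to at most 1")
  if (any(c(n_cows, n_herds, m_ir, m_snp) < 1)) stop("counts must be positive")
  if (n_qtl > m_snp) stop("n_qtl cannot exceed m_snp")
  if (is.null(n_sires)) n_sires <- max(5L, round(n_cows / 25))
  if (is.null(n_dams)) n_dams <- max(10L, round(n_cows / 1.6))
  structure(as.list(environment()), class = "sim_config")
}

# AR(1)-smoothed standard-normal curve over m channels, unit variance
smooth_curve <- function(m, rho = 0.97) {
  z <- stats::rnorm(m)
  x <- numeric(m)
  x[1] <- z[1]
  for (j in 2:m) x[j] <- rho * x[j - 1] + sqrt(1 - rho^2) * z[j]
  x
}

# row-wise AR(1) noise matrix, marginal sd `s`
ar1_noise <- function(n, m, rho, s) {
  E <- matrix(stats::rnorm(n * m), n, m)
  for (j in 2:m) E[, j] <- rho * E[, j - 1] + sqrt(1 - rho^2) * E[, j]
  E * s
}

#' Simulate a cow cohort with linked spectra, genotypes and traits
#'
#' Generates (i) a pedigree of founders plus one offspring generation under
#' random mating; (ii) genotypes gene-dropped from founder haplotypes at
#' Uniform(0.05, 0.5) reference frequencies, with `n_qtl` causal markers;
#' (iii) herds of rounded-normal size; (iv) days in milk and parity from
#' truncated normals; (v) spectra as a smooth baseline plus herd-specific
#' signature curves, a genetic loading curve, a milk-composition loading
#' curve and AR(1) channel noise; (vi) traits as mean + herd + DIM/parity
#' + genetic value + milk latent + residual, scaled to the target trait
#' means and SDs through theoretical (population) component variances so
#' realized moments fluctuate naturally. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list: `bundle` (a [cow_bundle()]) and `truth` (true genetic
#'   values, QTL ids/effects, herd effects, latent factors, shares).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_cows
    cow_ids <- sprintf("cow%04d", seq_len(n))

    ## herds: rounded-normal sizes, truncated at 3, repaired to sum n
    sizes <- pmax(3L, round(stats::rnorm(cfg$n_herds, cfg$cows_per_herd_mean,
                                         cfg$cows_per_herd_sd)))
    while (sum(sizes) != n) {
      i <- sample.int(cfg$n_herds, 1)
      if (sum(sizes) > n && sizes[i] > 3) sizes[i] <- sizes[i] - 1L
      else if (sum(sizes) < n) sizes[i] <- sizes[i] + 1L
    }
    herd_ids <- sprintf("herd%03d", seq_len(cfg$n_herds))
    herd <- rep(herd_ids, times = sizes)

    ## pedigree: founder sires/dams, cows are their offspring
    sires <- sprintf("S%03d", seq_len(cfg$n_sires))
    dams <- sprintf("D%04d", seq_len(cfg$n_dams))
    sire_of <- sample(sires, n, replace = TRUE)
    dam_of <- sample(dams, n, replace = TRUE)
    ped <- pedigree(data.frame(
      id = c(sires, dams, cow_ids),
      sire = c(rep(NA, cfg$n_sires + cfg$n_dams), sire_of),
      dam = c(rep(NA, cfg$n_sires + cfg$n_dams), dam_of)))

    ## genotypes: gene dropping from founder haplotypes
    m <- cfg$m_snp
    p <- stats::runif(m, 0.05, 0.5)
    founders <- c(sires, dams)
    nf <- length(founders)
    hapA <- matrix(stats::rbinom(nf * m, 1, rep(p, each = nf)), nf, m)
    hapB <- matrix(stats::rbinom(nf * m, 1, rep(p, each = nf)), nf, m)
    rownames(hapA) <- rownames(hapB) <- founders
    si <- match(sire_of, founders)
    di <- match(dam_of, founders)
    pickS <- matrix(stats::rbinom(n * m, 1, 0.5), n, m)
    pickD <- matrix(stats::rbinom(n * m, 1, 0.5), n, m)
    alleleS <- hapA[si, ] * (1 - pickS) + hapB[si, ] * pickS
    alleleD <- hapA[di, ] * (1 - pickD) + hapB[di, ] * pickD
    dos <- alleleS + alleleD
    # the panel emulates a post-QC chip: redraw columns that came out
    # monomorphic in the realized cohort (possible at small founder counts)
    for (tries in 1:25) {
      mono <- which(apply(dos, 2, function(x) length(unique(x)) == 1))
      if (!length(mono)) break
      for (j in mono) {
        hA <- stats::rbinom(nf, 1, p[j]); hB <- stats::rbinom(nf, 1, p[j])
        aS <- ifelse(stats::rbinom(n, 1, 0.5) == 1, hB[si], hA[si])
        aD <- ifelse(stats::rbinom(n, 1, 0.5) == 1, hB[di], hA[di])
        dos[, j] <- aS + aD
        hapA[, j] <- hA; hapB[, j] <- hB
      }
    }
    snp_ids <- sprintf("snp%05d", seq_len(m))
    dimnames(dos) <- list(cow_ids, snp_ids)

    ## genetic values: QTL + polygenic tail, theoretical unit variance
    qtl_idx <- sort(sample.int(m, cfg$n_qtl))
    # planted QTL: random sign, equal variance shares (each carries
    # qtl_share / n_qtl of the genetic variance)
    a_qtl <- sample(c(-1, 1), cfg$n_qtl, replace = TRUE) *
      sqrt((cfg$qtl_share / cfg$n_qtl) /
             (2 * p[qtl_idx] * (1 - p[qtl_idx])))
    poly_idx <- setdiff(seq_len(m), qtl_idx)
    a_poly <- stats::rnorm(length(poly_idx))
    vp <- sum(a_poly^2 * 2 * p[poly_idx] * (1 - p[poly_idx]))
    a_poly <- a_poly * sqrt((1 - cfg$qtl_share) / vp)
    gval <- as.numeric(dos[, qtl_idx, drop = FALSE] %*% a_qtl) +
      as.numeric(dos[, poly_idx, drop = FALSE] %*% a_poly)
    # founder-block sharing inflates the realized variance relative to the
    # HWE expectation; rescale to realized unit variance so the configured
    # h2 is the variance share actually simulated
    sc <- stats::sd(gval)
    gval <- (gval - mean(gval)) / sc
    a_qtl <- a_qtl / sc
    a_poly <- a_poly / sc

    ## on-farm covariates (truncated normals; the pre-truncation location
    ## is adjusted so the post-truncation mean hits the configured target)
    rtrunc <- function(n, mean, sd, lo, hi) {
      x <- stats::rnorm(n, mean, sd)
      while (any(bad <- x < lo | x > hi))
        x[bad] <- stats::rnorm(sum(bad), mean, sd)
      x
    }
    tn_mean <- function(mu, sd, lo, hi) {
      a <- (lo - mu) / sd; b <- (hi - mu) / sd
      mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
        (stats::pnorm(b) - stats::pnorm(a))
    }
    mu_dim <- stats::uniroot(function(mu)
      tn_mean(mu, cfg$dim_sd, 5, 600) - cfg$dim_mean,
      c(cfg$dim_mean - 3 * cfg$dim_sd, cfg$dim_mean + cfg$dim_sd))$root
    dim_days <- rtrunc(n, mu_dim, cfg$dim_sd, 5, 600)
    parity <- pmin(8L, pmax(1L, round(rtrunc(n, cfg$parity_mean,
                                             cfg$parity_sd, 0.5, 8.49))))
    onfarm <- data.frame(cow_id = cow_ids, herd = herd, dim = dim_days,
                         parity = parity, stringsAsFactors = FALSE)

    ## latent factors
    alpha_herd <- stats::rnorm(cfg$n_herds)          # trait herd effect
    hvec <- alpha_herd[match(herd, herd_ids)]
    milk <- stats::rnorm(n)                          # milk-composition latent
    dimz <- (dim_days - cfg$dim_mean) / cfg$dim_sd
    parz <- (parity - cfg$parity_mean) / cfg$parity_sd

    ## traits
    tt <- cfg$traits
    ntr <- nrow(tt)
    traits <- matrix(NA_real_, n, ntr, dimnames = list(cow_ids, tt$trait))
    bv <- matrix(0, n, ntr, dimnames = list(cow_ids, tt$trait))
    for (t in seq_len(ntr)) {
      resid_share <- 1 - cfg$h2[t] - cfg$herd_share - cfg$dim_share -
        cfg$parity_share - cfg$milk_share
      ystar <- sqrt(cfg$herd_share) * hvec +
        sqrt(cfg$h2[t]) * gval +
        sqrt(cfg$dim_share) * dimz +
        sqrt(cfg$parity_share) * parz +
        sqrt(cfg$milk_share) * milk +
        sqrt(resid_share) * stats::rnorm(n)
      traits[, t] <- tt$mean[t] + tt$sd[t] * ystar
      bv[, t] <- tt$sd[t] * sqrt(cfg$h2[t]) * gval
    }

    ## spectra
    mir <- cfg$m_ir
    wn <- seq(cfg$wn_max, cfg$wn_min, length.out = mir)
    base <- 0.8 * smooth_curve(mir) + 0.2
    L_g <- smooth_curve(mir)
    L_m <- smooth_curve(mir)
    herd_sig <- t(vapply(seq_len(cfg$n_herds),
                         function(i) smooth_curve(mir), numeric(mir)))
    spec <- matrix(base, n, mir, byrow = TRUE) +
      cfg$spectra_herd_loading * herd_sig[match(herd, herd_ids), ] +
      cfg$spectra_genetic_loading * outer(gval, L_g) +
      cfg$spectra_milk_loading * outer(milk, L_m) +
      ar1_noise(n, mir, cfg$ar1_rho, cfg$spectra_noise_sd)
    spectra <- spectra_matrix(spec, wavenumbers = wn, cow_ids = cow_ids)

    ## genotype missingness
    if (cfg$missing_rate > 0) {
      nmiss <- round(cfg$missing_rate * length(dos))
      dos[sample.int(length(dos), nmiss)] <- NA
    }
    genotypes <- genotype_matrix(dos, snp_ids = snp_ids, cow_ids = cow_ids)

    bundle <- cow_bundle(spectra, genotypes, ped, onfarm, traits)
    truth <- list(bv = bv, g = gval,
                  qtl_ids = snp_ids[qtl_idx], qtl_effects = a_qtl,
                  herd_effects = stats::setNames(alpha_herd, herd_ids),
                  milk = milk,
                  shares = list(h2 = cfg$h2, herd = cfg$herd_share,
                                dim = cfg$dim_share,
                                parity = cfg$parity_share,
                                milk = cfg$milk_share),
                  loadings = list(genetic = L_g, milk = L_m,
                                  herd_signatures = herd_sig),
                  seed = cfg$seed)
    list(bundle = bundle, truth = truth)
  })
}

#' Realized heritability of the simulated traits
#'
#' var(true genetic value) / var(trait) on the realized sample, per trait.
#'
#' @param bundle simulated [cow_bundle()].
#' @param truth matching truth list from [simulate_dataset()].
#' @return named numeric vector.
#' @export
realized_h2 <- function(bundle, truth) {
  vy <- apply(bundle$traits, 2, stats::var)
  if (any(vy == 0)) stop("zero trait variance")
  apply(truth$bv, 2, stats::var) / vy
}

#' Write / read a simulated bundle as delimited text
#'
#' Writes spectra.csv, genotypes.csv, pedigree.csv, onfarm.csv, traits.csv
#' and (when truth is given) truth.json into `dir`.
#'
#' @param sim result of [simulate_dataset()], or a bare [cow_bundle()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly (write); a `cow_bundle` (read).
#' @name bundle_io
#' @export
write_bundle <- function(sim, dir) {
  bundle <- if (inherits(sim, "cow_bundle")) sim else sim$bundle
  truth <- if (inherits(sim, "cow_bundle")) NULL else sim$truth
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_csv(bundle$spectra$values, file.path(dir, "spectra.csv"))
  if (!is.null(bundle$genotypes))
    write_matrix_csv(bundle$genotypes$dosages, file.path(dir, "genotypes.csv"))
  if (!is.null(bundle$pedigree)) {
    pd <- as.data.frame(bundle$pedigree)
    pd[is.na(pd)] <- "0"
    data.table::fwrite(pd, file.path(dir, "pedigree.csv"))
  }
  data.table::fwrite(bundle$onfarm, file.path(dir, "onfarm.csv"))
  write_matrix_csv(bundle$traits, file.path(dir, "traits.csv"))
  if (!is.null(truth)) {
    tr <- truth
    tr$loadings <- NULL  # bulky, reproducible from the seed
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname bundle_io
#' @export
read_bundle <- function(dir) {
  spectra <- read_spectra(file.path(dir, "spectra.csv"))
  gpath <- file.path(dir, "genotypes.csv")
  genotypes <- if (file.exists(gpath)) read_genotypes(gpath) else NULL
  ppath <- file.path(dir, "pedigree.csv")
  ped <- if (file.exists(ppath)) read_pedigree(ppath) else NULL
  onfarm <- read_onfarm(file.path(dir, "onfarm.csv"))
  traits <- read_traits(file.path(dir, "traits.csv"))
  cow_bundle(spectra, genotypes, ped, onfarm, traits)
}
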