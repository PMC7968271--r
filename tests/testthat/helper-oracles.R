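# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (brute-force loops, exhaustive enumeration,
# direct linear solves).

# --- exhaustive gene-dropping oracle for the numerator relationship matrix.
# Founders (or unknown-parent slots) receive unique alleles; every possible
# inheritance pattern is enumerated, and A_ij = 2 * mean kinship over
# patterns. Exact (dyadic rationals) for small pedigrees.
oracle_A_genedrop <- function(ped_df) {
  ped <- spectrakin::pedigree(ped_df)
  n <- nrow(ped)
  # topological order by repeated sweeps
  placed <- rep(FALSE, n)
  ord <- integer(0)
  while (length(ord) < n) {
    progress <- FALSE
    for (i in seq_len(n)) {
      if (placed[i]) next
      par <- c(ped$sire[i], ped$dam[i])
      par <- par[!is.na(par)]
      if (all(par %in% ped$id[placed]) || !length(par)) {
        placed[i] <- TRUE; ord <- c(ord, i); progress <- TRUE
      }
    }
    if (!progress) stop("cyclic pedigree in oracle")
  }
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  # binary choice per known parent link
  links <- matrix(0L, 0, 2)  # (individual, slot 1=sire 2=dam)
  for (i in ord) {
    if (!is.na(si[i])) links <- rbind(links, c(i, 1L))
    if (!is.na(di[i])) links <- rbind(links, c(i, 2L))
  }
  L <- nrow(links)
  npat <- 2^L
  A <- matrix(0, n, n)
  for (pat in seq_len(npat) - 1L) {
    bits <- if (L > 0) as.integer(intToBits(pat))[seq_len(L)] else integer(0)
    al <- matrix(0L, n, 2)
    nxt <- 1L
    li <- 1L
    for (i in ord) {
      for (slot in 1:2) {
        par <- if (slot == 1) si[i] else di[i]
        if (is.na(par)) {
          al[i, slot] <- nxt; nxt <- nxt + 1L
        } else {
          al[i, slot] <- al[par, 1L + bits[li]]
          li <- li + 1L
        }
      }
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      f <- (sum(outer(al[i, ], al[j, ], "==")) / 4)
      A[i, j] <- A[i, j] + 2 * f / npat
    }
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# random valid (acyclic) pedigree of given size: parents always precede
# offspring, possibly unknown
random_pedigree <- function(size) {
  id <- paste0("i", seq_len(size))
  sire <- dam <- rep(NA_character_, size)
  for (i in seq_len(size)) {
    if (i >= 2 && runif(1) < 0.7) {
      sire[i] <- sample(id[seq_len(i - 1)], 1)
      rest <- setdiff(id[seq_len(i - 1)], sire[i])
      if (length(rest) && runif(1) < 0.8) dam[i] <- sample(rest, 1)
    }
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# --- direct Henderson mixed-model-equation solve for
# y = X b + sum_k u_k + e, u_k ~ N(0, K_k s2u_k), e ~ N(0, I s2e).
# Returns b and the stacked u_k (one block per kernel).
oracle_mme <- function(y, X, Ks, s2u, s2e) {
  n <- length(y); p <- ncol(X); nk <- length(Ks)
  dim_all <- p + nk * n
  C <- matrix(0, dim_all, dim_all)
  rhs <- numeric(dim_all)
  C[1:p, 1:p] <- crossprod(X) / s2e
  rhs[1:p] <- crossprod(X, y) / s2e
  for (k in seq_len(nk)) {
    rows <- p + (k - 1) * n + seq_len(n)
    C[1:p, rows] <- t(X) / s2e
    C[rows, 1:p] <- X / s2e
    C[rows, rows] <- diag(n) / s2e + solve(Ks[[k]]) / s2u[k]
    rhs[rows] <- y / s2e
    for (k2 in seq_len(nk)) {
      if (k2 == k) next
      rows2 <- p + (k2 - 1) * n + seq_len(n)
      C[rows, rows2] <- diag(n) / s2e
    }
  }
  sol <- solve(C, rhs)
  list(b = sol[1:p],
       u = lapply(seq_len(nk),
                  function(k) sol[p + (k - 1) * n + seq_len(n)]))
}

# missing-record variant: kernels span n_all individuals but only `obs`
# rows carry phenotypes; returns effects for all individuals
oracle_mme_missing <- function(y_obs, X_all, obs, Ks_all, s2u, s2e) {
  n_all <- nrow(X_all); p <- ncol(X_all); nk <- length(Ks_all)
  Z <- matrix(0, length(obs), n_all)
  Z[cbind(seq_along(obs), obs)] <- 1
  Xo <- X_all[obs, , drop = FALSE]
  dim_all <- p + nk * n_all
  C <- matrix(0, dim_all, dim_all)
  rhs <- numeric(dim_all)
  C[1:p, 1:p] <- crossprod(Xo) / s2e
  rhs[1:p] <- crossprod(Xo, y_obs) / s2e
  ZtZ <- crossprod(Z)
  for (k in seq_len(nk)) {
    rows <- p + (k - 1) * n_all + seq_len(n_all)
    C[1:p, rows] <- crossprod(Xo, Z) / s2e
    C[rows, 1:p] <- t(C[1:p, rows])
    C[rows, rows] <- ZtZ / s2e + solve(Ks_all[[k]]) / s2u[k]
    rhs[rows] <- crossprod(Z, y_obs) / s2e
    for (k2 in seq_len(nk)) {
      if (k2 == k) next
      rows2 <- p + (k2 - 1) * n_all + seq_len(n_all)
      C[rows, rows2] <- ZtZ / s2e
    }
  }
  sol <- solve(C, rhs)
  list(b = sol[1:p],
       u = lapply(seq_len(nk),
                  function(k) sol[p + (k - 1) * n_all + seq_len(n_all)]))
}

# batch-means Monte Carlo standard error for a single chain
batch_se <- function(x, nbatch = 20) {
  nb <- min(nbatch, max(2, floor(length(x) / 5)))
  bs <- floor(length(x) / nb)
  bm <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
               numeric(1))
  sd(bm) / sqrt(nb)
}

# a hand-built kernel_fit (documented structure) for prediction-formula
# tests where exact effect solutions come from an oracle
manual_kernel_fit <- function(b_hat, u_hat, X_names, y) {
  structure(list(b_hat = b_hat, u_hat = u_hat,
                 kernel_names = names(u_hat),
                 X_names = X_names, y = y,
                 varcomp = NULL, chains = NULL,
                 mcmc_meta = list()),
            class = "kernel_fit")
}

# small well-conditioned spectra-like matrix (m > n so S is invertible)
rand_spectra <- function(n, m, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * m), n, m)
    colnames(x) <- seq(5000, 1000, length.out = m)
    rownames(x) <- sprintf("cow%03d", seq_len(n))
    x
  })
}

# quick desk simulation shared by several tests
desk_sim <- function(seed = 11, ...) {
  simulate_dataset(sim_config(desk = TRUE, seed = seed, ...))
}
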