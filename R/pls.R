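#' Principal-component features from a relationship matrix
#'
#' Eigenvectors scaled by the square roots of their eigenvalues, retaining
#' the smallest number of components whose cumulative eigenvalue share
#' strictly exceeds `variance_target`. Used to feed genomic or pedigree
#' information into the PLS baseline.
#'
#' @param k a positive semidefinite [relationship_matrix()] (or matrix).
#' @param variance_target cumulative variance share to exceed, in (0, 1);
#'   default 0.80.
#' @return list: `scores` (n x r matrix, rows named by individual),
#'   `n_retained`, `eigenvalues`, `share` (cumulative shares).
#' @export
pc_features <- function(k, variance_target = 0.80) {
  if (variance_target <= 0 || variance_target >= 1)
    stop("variance_target must be in (0, 1)")
  ids <- if (inherits(k, "relationship_matrix")) k$ids else rownames(k)
  e <- kernel_eigen(k, "pc_features kernel")
  ev <- e$values
  tot <- sum(ev)
  if (tot <= 0) stop("kernel has no positive eigenvalues")
  cshare <- cumsum(ev) / tot
  r <- which(cshare > variance_target)[1]
  scores <- e$vectors[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(r)]), r)
  rownames(scores) <- ids
  colnames(scores) <- paste0("PC", seq_len(r))
  list(scores = scores, n_retained = r, eigenvalues = ev, share = cshare)
}

# NIPALS PLS1 on centered/scaled X and centered y; returns scores T,
# weights W, X-loadings P, y-loadings q for ncomp components.
nipals_pls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  TT <- matrix(0, n, ncomp); W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  Xk <- X; yk <- y
  actual <- 0
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xk, yk)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xk %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pk <- crossprod(Xk, t) / tt
    qk <- sum(yk * t) / tt
    Xk <- Xk - tcrossprod(t, pk)
    yk <- yk - t * qk
    TT[, k] <- t; W[, k] <- w; P[, k] <- pk; q[k] <- qk
    actual <- k
  }
  list(T = TT[, seq_len(actual), drop = FALSE],
       W = W[, seq_len(actual), drop = FALSE],
       P = P[, seq_len(actual), drop = FALSE],
       q = q[seq_len(actual)], ncomp = actual)
}

# regression coefficients (on the standardized scale) for a component count
pls_coef <- function(dec, ncomp) {
  W <- dec$W[, seq_len(ncomp), drop = FALSE]
  P <- dec$P[, seq_len(ncomp), drop = FALSE]
  q <- dec$q[seq_len(ncomp)]
  W %*% solve(crossprod(P, W), q)
}

#' Fit the partial least squares baseline
#'
#' NIPALS decomposition of the column-concatenated (standardized) predictor
#' blocks; the number of latent variables minimizing the inner
#' cross-validation root mean squared error is selected, capped at
#' `max_components` (default 50) and at n - 1.
#'
#' @param y phenotype vector (training rows).
#' @param X predictor matrix, blocks already column-concatenated.
#' @param max_components largest admissible latent-variable count.
#' @param inner_folds folds for the inner selection CV (default 10, min 2).
#' @param seed seed for the inner fold assignment.
#' @return object of class `pls_fit`: selected `n_components`, training
#'   column `stats`, `coef` and intercept, NIPALS `scores`/weights, and the
#'   inner RMSE path.
#' @export
fit_pls <- function(y, X, max_components = 50, inner_folds = 10, seed = 1L) {
  if (inner_folds < 2) stop("at least 2 inner folds are required")
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stats <- standardize_columns(X)
  Xs <- stats$values
  ymean <- mean(y)
  yc <- y - ymean
  ncmax <- min(max_components, n - 1, ncol(Xs))

  folds <- withr::with_seed(seed, sample(rep(seq_len(inner_folds),
                                             length.out = n)))
  sse <- numeric(ncmax)
  cnt <- 0
  for (f in seq_len(inner_folds)) {
    tr <- folds != f
    if (sum(tr) < 2 || sum(!tr) < 1) next
    st_f <- standardize_columns(X[tr, , drop = FALSE])
    ncf <- min(ncmax, sum(tr) - 1, ncol(st_f$values))
    dec <- nipals_pls1(st_f$values, yc_f <- y[tr] - mean(y[tr]), ncf)
    Xt <- apply_column_stats(X[!tr, , drop = FALSE], st_f)
    for (k in seq_len(ncmax)) {
      kk <- min(k, dec$ncomp)
      pred <- mean(y[tr]) + as.numeric(Xt %*% pls_coef(dec, kk))
      sse[k] <- sse[k] + sum((y[!tr] - pred)^2)
    }
    cnt <- cnt + sum(!tr)
  }
  rmse <- sqrt(sse / cnt)
  nsel <- which.min(rmse)  # smallest index wins ties

  dec <- nipals_pls1(Xs, yc, ncmax)
  nsel <- min(nsel, dec$ncomp)
  coef <- pls_coef(dec, nsel)
  structure(list(n_components = nsel,
                 max_components = max_components,
                 coef = coef,
                 intercept = ymean,
                 stats = stats,
                 scores = dec$T,
                 weights = dec$W,
                 loadings = dec$P,
                 q = dec$q,
                 rmse_path = rmse,
                 fitted = ymean + as.numeric(Xs %*% coef)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d latent variable(s) selected (cap %d)\n",
              x$n_components, x$max_components))
  invisible(x)
}

#' Predict from a PLS fit
#'
#' Test columns are standardized with the training statistics; the
#' training-selected latent-variable count is applied unchanged.
#'
#' @param fit a `pls_fit`.
#' @param X_tst test predictor matrix with the training columns.
#' @return numeric prediction vector.
#' @export
predict_pls <- function(fit, X_tst) {
  stopifnot(inherits(fit, "pls_fit"))
  Xs <- apply_column_stats(as.matrix(X_tst), fit$stats)
  if (ncol(Xs) != nrow(fit$coef)) stop("column mismatch with training design")
  fit$intercept + as.numeric(Xs %*% fit$coef)
}
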