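# Independent oracles used to cross-check the fitting and ranking code.
# These deliberately avoid the code paths they check: generic numerical
# minimization for the least-squares fits, projected gradient for the
# non-negative fit, and exhaustive rank-assignment enumeration for the
# rank-sum P-value.

# generic numerical minimizer of the residual-norm objective (multi-start)
olsOracle <- function(X, d, nStarts = 5) {
  obj <- function(w) sum((d - X %*% w)^2)
  grad <- function(w) drop(2 * crossprod(X, X %*% w - d))
  starts <- c(list(rep(0, ncol(X))),
              lapply(seq_len(nStarts - 1), function(i) rnorm(ncol(X))))
  fits <- lapply(starts, function(s)
    optim(s, obj, grad, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-15)))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  best$par
}

# projected-gradient non-negative least squares
nnlsOracle <- function(X, d, maxIter = 200000, tol = 1e-13) {
  L <- max(eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) return(rep(0, ncol(X)))
  w <- rep(0, ncol(X))
  for (i in seq_len(maxIter)) {
    wn <- pmax(0, w - drop(crossprod(X, X %*% w - d)) / L)
    if (max(abs(wn - w)) < tol) return(wn)
    w <- wn
  }
  w
}

# exhaustive two-sided rank-sum P-value over all rank assignments
wmwEnumOracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  us <- apply(combn(n + m, n), 2, function(idx) sum(idx) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= u), mean(us >= u)))
}

# random regression instance with unit-norm columns
randomInstance <- function(S, M, noise = 1) {
  X <- matrix(rnorm(S * M), S, M)
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  colnames(X) <- sprintf("H%d", seq_len(M))
  list(X = X, d = rnorm(S, sd = noise))
}

# small expression dataset with named genes, no missing values
tinyDataset <- function(nGenes = 12, S = 8, id = "toy", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(nGenes * S, mean = 10), nGenes, S,
              dimnames = list(sprintf("G%02d", seq_len(nGenes)),
                              sprintf("s%d", seq_len(S))))
  ExpressionDataset(m, id)
}
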