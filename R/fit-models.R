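#' L1-rescale a weight vector
#'
#' Divides each coefficient by the sum of absolute coefficients so that
#' weight vectors are comparable across datasets (the rescaled vector has
#' unit L1 norm). An all-zero vector has no defined rescaling and returns
#' \code{NULL}: such degenerate fits are excluded from pooling rather than
#' recorded as zeros, which would spike the null distribution at 0.
#'
#' @param raw numeric coefficient vector (finite).
#' @return Rescaled vector of the same length, or \code{NULL} if degenerate.
#' @examples
#' rescaleL1(c(2, -2))  # 0.5 -0.5
#' @export
rescaleL1 <- function(raw) {
  if (!is.numeric(raw) || anyNA(raw) || any(!is.finite(raw)))
    stop("'raw' must be finite numeric")
  s <- sum(abs(raw))
  if (s <= .Machine$double.eps * length(raw)) return(NULL)
  raw / s
}

# minimum-norm least squares via SVD; the pseudo-inverse fallback makes
# collinear or underdetermined designs (S < M, duplicated hosts) well-defined
.lsMinNorm <- function(X, d) {
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(rep(0, ncol(X)))
  if (!all(keep))
    warning("rank-deficient design (", sum(keep), "/", ncol(X),
            " singular values kept); returning the minimum-norm solution")
  drop(s$v[, keep, drop = FALSE] %*%
         (crossprod(s$u[, keep, drop = FALSE], d) / s$d[keep]))
}

.newFit <- function(method, hosts, raw, flagged = character()) {
  raw <- as.numeric(raw)
  names(raw) <- hosts
  rescaled <- rescaleL1(raw)
  if (!is.null(rescaled)) names(rescaled) <- hosts
  list(method = method, hostGenes = hosts, raw = raw, rescaled = rescaled,
       degenerate = is.null(rescaled), flagged = flagged)
}

.checkXd <- function(X, d) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(d))
    stop("dimension mismatch: X has ", nrow(X), " rows but d has length ",
         length(d))
  if (ncol(X) < 1L) stop("X needs at least one regressor column")
  X
}

#' Fit the unconstrained linear model (ULM) for one target and dataset
#'
#' Ordinary least squares fit of the target's down-regulation vector on the
#' unit-norm host profiles: \code{raw = argmin_w || d - X w ||_2}. This is
#' the maximum-likelihood estimate under spherical Gaussian noise. Solved via
#' the singular value decomposition, which returns the minimum-norm solution
#' whenever \code{X'X} is singular (collinear hosts, fewer samples than
#' hosts). No intercept is fitted: the response is already referenced to the
#' dataset-wide mean by construction. A positive weight means the host's
#' profile tracks the target's down-regulation, i.e. predicted repression by
#' the host's intronic miRNA(s).
#'
#' @param X numeric matrix, samples x hosts, of unit-norm host profiles
#'   (column names = host gene symbols).
#' @param d down-regulation vector from \code{\link{computeDownregulation}}.
#' @return List with elements \code{method}, \code{hostGenes}, \code{raw},
#'   \code{rescaled} (unit L1 norm; \code{NULL} if degenerate),
#'   \code{degenerate}, \code{flagged}.
#' @seealso \code{\link{fitCLM}}, \code{\link{fitCORR}}, \code{\link{rescaleL1}}
#' @export
fitULM <- function(X, d) {
  X <- .checkXd(X, d)
  .newFit("ULM", colnames(X), .lsMinNorm(X, d))
}

#' Fit the constrained linear model (CLM)
#'
#' Non-negative least squares variant of \code{\link{fitULM}}: weights are
#' constrained to be >= 0, insisting that miRNAs act only to down-regulate
#' their targets. The unconstrained fit is preferred by default because
#' relaxing the constraint simplifies estimation without changing the
#' significant calls appreciably; the CLM is provided for comparison.
#'
#' @inheritParams fitULM
#' @return As \code{\link{fitULM}}, with \code{raw >= 0}.
#' @export
fitCLM <- function(X, d) {
  X <- .checkXd(X, d)
  w <- pracma::lsqnonneg(X, as.numeric(d))$x
  .newFit("CLM", colnames(X), pmax(w, 0))
}

#' Correlation baseline (CORR)
#'
#' Replaces regression weights by the per-host Pearson correlation between
#' the host profile and the target's down-regulation vector, mimicking
#' inverse-correlation target predictors within the same enrichment
#' framework (positive values mean predicted repression, as for the linear
#' models, since the response is the down-regulation). A constant host
#' column or constant response yields coefficient 0 and is flagged.
#'
#' @inheritParams fitULM
#' @return As \code{\link{fitULM}}; \code{flagged} names hosts whose
#'   coefficient was zeroed for zero variance.
#' @export
fitCORR <- function(X, d) {
  X <- .checkXd(X, d)
  sdx <- apply(X, 2L, stats::sd)
  sdd <- stats::sd(d)
  flagged <- colnames(X)[sdx == 0]
  if (sdd == 0) flagged <- colnames(X)
  r <- numeric(ncol(X))
  ok <- sdx > 0 & sdd > 0
  if (any(ok)) r[ok] <- drop(stats::cor(X[, ok, drop = FALSE], as.numeric(d)))
  .newFit("CORR", colnames(X), r, flagged = flagged)
}

.fitMethod <- function(method, X, d) {
  switch(method, ULM = fitULM(X, d), CLM = fitCLM(X, d), CORR = fitCORR(X, d),
         stop("unknown method '", method, "'"))
}

#' Fit weights for all targets across a compendium
#'
#' Runs the chosen model for every (target, dataset) combination. Within
#' each dataset, hosts absent from the (filtered) expression matrix are
#' masked from that dataset's design only; a design whose hosts are all
#' absent, a target absent from the dataset, and degenerate (all-zero) fits
#' are skipped. Down-regulation vectors use the dataset's full filtered gene
#' universe.
#'
#' @param datasets list of filtered \linkS4class{ExpressionDataset}.
#' @param designs named list of \linkS4class{TargetDesign}
#'   (see \code{\link{buildDesigns}}).
#' @param method "ULM", "CLM" or "CORR".
#' @return data.frame with one row per retained (target, host, dataset)
#'   coefficient: method, dataset, target, host, raw, rescaled.
#' @export
fitWeightTable <- function(datasets, designs, method = c("ULM", "CLM", "CORR")) {
  method <- match.arg(method)
  allHosts <- sort(unique(unlist(lapply(designs, hostGenes))))
  out <- vector("list", length(datasets) * length(designs))
  i <- 0L
  for (ds in datasets) {
    m <- exprValues(ds)
    Xall <- .hostProfileMatrix(ds, allHosts)
    if (is.null(Xall)) next
    mu <- colMeans(m)
    for (design in designs) {
      tg <- targetGene(design)
      if (!(tg %in% rownames(m))) next
      hs <- intersect(hostGenes(design), colnames(Xall))
      if (!length(hs)) next
      d <- mu - m[tg, ]
      fit <- .fitMethod(method, Xall[, hs, drop = FALSE], d)
      if (fit$degenerate) next
      i <- i + 1L
      out[[i]] <- data.frame(method = method, dataset = datasetId(ds),
                             target = tg, host = hs,
                             raw = unname(fit$raw),
                             rescaled = unname(fit$rescaled),
                             stringsAsFactors = FALSE)
    }
  }
  if (!i)
    return(data.frame(method = character(), dataset = character(),
                      target = character(), host = character(),
                      raw = numeric(), rescaled = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(i)])
  rownames(res) <- NULL
  res
}

#' Write or read a weight table as TSV
#'
#' @param wt weight table from \code{\link{fitWeightTable}}.
#' @param path output file.
#' @return \code{writeWeightTable} returns \code{path} invisibly;
#'   \code{readWeightTable} returns the data.frame.
#' @export
writeWeightTable <- function(wt, path) {
  utils::write.table(wt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWeightTable
#' @export
readWeightTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
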