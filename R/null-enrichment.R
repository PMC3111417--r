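#' Permute host-gene labels for one design
#'
#' Draws replacement hosts for a design's columns from the dataset's host
#' universe: each column is assigned a uniformly drawn *different* host,
#' distinct within the design (no column keeps its own label and no host is
#' used twice). This breaks the host-profile / target association while
#' preserving the multiset of available host profiles, which is what the
#' empirical null distribution requires.
#'
#' Randomness is taken from R's global RNG; seed it (once, at pipeline
#' level) for reproducibility.
#'
#' @param hosts character vector of the design's host labels.
#' @param universe character vector of all candidate host labels available in
#'   the dataset (must contain >= 2 hosts).
#' @param scope "universe" draws replacements from the whole host universe
#'   (default); "design" permutes only within the design's own columns
#'   (a derangement of \code{hosts}).
#' @return Character vector of replacement hosts, aligned with \code{hosts}.
#' @export
permuteHosts <- function(hosts, universe, scope = c("universe", "design")) {
  scope <- match.arg(scope)
  if (scope == "design") universe <- hosts
  universe <- unique(universe)
  if (length(universe) < 2L)
    stop("permutation impossible: host universe has fewer than 2 hosts")
  if (length(hosts) > length(universe))
    stop("design has more columns than the host universe")
  for (i in seq_len(10000L)) {
    cand <- sample(universe, length(hosts))
    if (!any(cand == hosts)) return(cand)
  }
  stop("could not find a fixed-point-free host relabelling")
}

#' Build the pooled empirical permutation null
#'
#' For every (target, dataset) model and each of \code{nPerms} permutations,
#' the host labels are permuted (\code{\link{permuteHosts}}), the model is
#' refitted, and the L1-rescaled coefficients are added to the pool. All
#' weights produced this way form the empirical null distribution; the
#' per-pair permuted samples (indexed by the original host label) are
#' retained for computing the permuted-control Q values. Degenerate permuted
#' fits contribute nothing.
#'
#' @inheritParams fitWeightTable
#' @param nPerms permutations per (target, dataset); the default single
#'   permutation mirrors one permuted solve per dataset, larger values
#'   smooth the pool.
#' @param seed optional integer seed (set once before all draws). \code{NULL}
#'   leaves the RNG state alone.
#' @param scope see \code{\link{permuteHosts}}.
#' @return A \linkS4class{NullPool}.
#' @export
buildNullPool <- function(datasets, designs, method = c("ULM", "CLM", "CORR"),
                          nPerms = 1L, seed = NULL,
                          scope = c("universe", "design")) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (!is.null(seed)) set.seed(seed)
  allHosts <- sort(unique(unlist(lapply(designs, hostGenes))))
  out <- vector("list", length(datasets) * length(designs) * nPerms)
  i <- 0L
  for (ds in datasets) {
    m <- exprValues(ds)
    Xall <- .hostProfileMatrix(ds, allHosts)
    if (is.null(Xall)) next
    universe <- colnames(Xall)
    mu <- colMeans(m)
    for (design in designs) {
      tg <- targetGene(design)
      if (!(tg %in% rownames(m))) next
      hs <- intersect(hostGenes(design), universe)
      if (!length(hs)) next
      d <- mu - m[tg, ]
      for (p in seq_len(nPerms)) {
        repl <- permuteHosts(hs, universe, scope = scope)
        fit <- .fitMethod(method, Xall[, repl, drop = FALSE], d)
        if (fit$degenerate) next
        i <- i + 1L
        out[[i]] <- data.frame(dataset = datasetId(ds), target = tg,
                               host = hs, perm = p,
                               rescaled = unname(fit$rescaled),
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (!i) stop("empty null pool: no non-degenerate permuted fit")
  pw <- do.call(rbind, out[seq_len(i)])
  rownames(pw) <- NULL
  new("NullPool", method = method, pool = pw$rescaled, permWeights = pw,
      nPerms = as.integer(nPerms),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      scope = scope)
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum P-value
#'
#' Compares a weight sample against the pooled null by the two-sided
#' rank-sum test. The exact null distribution of the U statistic is used
#' when \code{min(n, m) <= 8} and the combined data are tie-free; otherwise
#' the normal approximation with midranks, tie-corrected variance and
#' continuity correction is used. The two-sided P doubles the smaller tail
#' and is capped at 1.
#'
#' @param sample numeric vector (>= 1 value).
#' @param pool numeric vector (>= 1 value).
#' @return P-value in (0, 1].
#' @examples
#' wmwTwoSided(1:3, 4:6)  # 0.1: the extreme U in 1 of choose(6,3)=20, doubled
#' @export
wmwTwoSided <- function(sample, pool) {
  n <- length(sample); m <- length(pool)
  if (!n || !m) stop("'sample' and 'pool' must each have >= 1 element")
  comb <- c(sample, pool)
  if (anyNA(comb)) stop("missing values in rank-sum input")
  r <- rank(comb)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(comb))
  if (min(n, m) <= 8L && !ties) {
    lower <- stats::pwilcox(U, n, m)
    upper <- if (U >= 1) 1 - stats::pwilcox(U - 1, n, m) else 1
    return(min(1, 2 * min(lower, upper)))
  }
  N <- n + m
  tied <- table(r)
  sigma <- sqrt((n * m / 12) * ((N + 1) - sum(tied^3 - tied) / (N * (N - 1))))
  if (sigma == 0) return(1)
  z <- U - n * m / 2
  z <- (z - sign(z) * 0.5) / sigma
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Score one host-target pair against the null pool
#'
#' Computes the pair's enrichment P-value (real weights vs pool), the
#' permuted-control Q-value (the pair's own permuted weights vs pool), and
#' the repression sign: "negative" (i.e. predicted repression) when the mean
#' real weight exceeds the null mean, "non-negative" otherwise.
#'
#' @param realWeights the pair's rescaled weights across datasets.
#' @param permWeights the pair's permuted rescaled weights across datasets.
#' @param pool a \linkS4class{NullPool} (or numeric pool vector).
#' @return One-row data.frame: n_datasets, p_real, p_perm, mean_weight,
#'   null_mean, sign.
#' @export
scorePair <- function(realWeights, permWeights, pool) {
  if (is(pool, "NullPool")) pool <- nullWeights(pool)
  if (!length(realWeights)) stop("pair has no real weights")
  pPerm <- if (length(permWeights)) wmwTwoSided(permWeights, pool) else NA_real_
  mw <- mean(realWeights)
  nm <- mean(pool)
  data.frame(n_datasets = length(realWeights),
             p_real = wmwTwoSided(realWeights, pool),
             p_perm = pPerm,
             mean_weight = mw, null_mean = nm,
             sign = if (mw > nm) "negative" else "non-negative",
             stringsAsFactors = FALSE)
}

#' Score all host-target pairs of a weight table
#'
#' Applies \code{\link{scorePair}} to every (host, target) pair with at
#' least one real weight, using the pooled permutation null of the matching
#' method.
#'
#' @param weightTable data.frame from \code{\link{fitWeightTable}}.
#' @param pool \linkS4class{NullPool} built with the same method.
#' @return data.frame with columns method, host, target, n_datasets, p_real,
#'   p_perm, mean_weight, null_mean, sign, ordered by (target, host).
#' @export
scoreInteractions <- function(weightTable, pool) {
  stopifnot(is(pool, "NullPool"))
  if (!nrow(weightTable)) stop("empty weight table")
  if (!all(weightTable$method == pool@method))
    stop("weight table method does not match null pool method '",
         pool@method, "'")
  poolW <- pool@pool
  key <- paste(weightTable$target, weightTable$host, sep = "\r")
  pkey <- paste(pool@permWeights$target, pool@permWeights$host, sep = "\r")
  realSplit <- split(weightTable$rescaled, key)
  permSplit <- split(pool@permWeights$rescaled, pkey)
  keys <- sort(names(realSplit))
  rows <- lapply(keys, function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    s <- scorePair(realSplit[[k]], permSplit[[k]], poolW)
    cbind(data.frame(method = pool@method, host = parts[2L],
                     target = parts[1L], stringsAsFactors = FALSE), s)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$target, res$host), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an interaction score table as TSV
#'
#' @param scores data.frame from \code{\link{scoreInteractions}} (optionally
#'   annotated by \code{\link{classifyInteractions}}).
#' @param path output file.
#' @export
writeScores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
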