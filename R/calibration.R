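#' ROC curve of real vs permuted enrichment P-values
#'
#' Builds the receiver operating characteristic used to pick the
#' significance cutoff: discriminant scores are -log10 P, positives are the
#' real-pair P-values and negatives the permuted-control Q-values. A pair is
#' predicted positive at threshold t when its -log10 P >= t. Thresholds run
#' over the observed scores (ties processed together), so the curve starts
#' at (0, 0) for an unattainably strict threshold and ends at (1, 1).
#'
#' @param pReal numeric vector of real P-values in (0, 1].
#' @param pPerm numeric vector of permuted Q-values in (0, 1].
#' @return data.frame (threshold, fpr, tpr) with attribute \code{"auc"}
#'   (trapezoidal area under the curve).
#' @export
buildRoc <- function(pReal, pPerm) {
  if (!length(pReal) || !length(pPerm))
    stop("both score sets must be nonempty")
  pos <- -log10(pReal)
  neg <- -log10(pPerm)
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg >= t), 0)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                              utils::tail(roc$tpr, -1)) / 2)
  attr(roc, "auc") <- auc
  roc
}

#' Area under a ROC curve
#'
#' @param roc data.frame from \code{\link{buildRoc}}.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(roc) attr(roc, "auc")

#' Choose the significance cutoff from a ROC curve
#'
#' Returns the least stringent P-value cutoff whose false-positive rate
#' (fraction of permuted-control pairs called significant) does not exceed
#' \code{1 - targetSpecificity}: thresholds on -log10 P are scanned in
#' ascending order over observed values and the smallest one achieving the
#' specificity is reported. If no threshold achieves it, the most stringent
#' observed threshold is returned with a warning.
#'
#' For comparability with a conventional fixed cutoff, the pipeline default
#' bypasses the ROC and uses P <= 0.01 (see \code{\link{runPipeline}}).
#'
#' @param roc data.frame from \code{\link{buildRoc}}.
#' @param targetSpecificity required specificity on the permuted controls
#'   (default 1.0, i.e. zero observed false positives).
#' @return P-value cutoff (numeric scalar), with attributes
#'   \code{"threshold"} (the -log10 P threshold), \code{"sensitivity"} and
#'   \code{"fpr"} at that threshold.
#' @export
chooseCutoff <- function(roc, targetSpecificity = 1.0) {
  stopifnot(is.data.frame(roc), targetSpecificity >= 0, targetSpecificity <= 1)
  finite <- roc[is.finite(roc$threshold), , drop = FALSE]
  finite <- finite[order(finite$threshold), , drop = FALSE]
  ok <- finite$fpr <= 1 - targetSpecificity
  if (any(ok)) {
    row <- finite[which(ok)[1L], ]
  } else {
    warning("requested specificity unachievable; using the most stringent ",
            "observed threshold")
    row <- finite[nrow(finite), ]
  }
  structure(10^(-row$threshold), threshold = row$threshold,
            sensitivity = row$tpr, fpr = row$fpr)
}

#' Flag significant and negative interactions
#'
#' Marks a pair significant when its real P-value is at or below the cutoff,
#' and negative (predicted repression) when it is significant and its mean
#' weight across datasets exceeds the null mean.
#'
#' @param scores data.frame from \code{\link{scoreInteractions}}.
#' @param cutoff P-value cutoff (default 0.01).
#' @return \code{scores} with logical columns \code{significant} and
#'   \code{negative} appended.
#' @export
classifyInteractions <- function(scores, cutoff = 0.01) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff <= 1)
  scores$significant <- scores$p_real <= as.numeric(cutoff)
  scores$negative <- scores$significant & scores$sign == "negative"
  scores
}

#' Classify hosts as good or bad expression surrogates
#'
#' Summarizes each host's significant interactions and calls the host a
#' \code{good_surrogate} when its significant interactions are
#' majority-negative (strictly more negative than non-negative ones: a tie
#' is called \code{bad_surrogate}, conservatively, since good-surrogate
#' status licenses downstream target claims), a \code{bad_surrogate} when
#' not, and \code{uninformative} when it has no significant interaction at
#' all.
#'
#' @param scores annotated data.frame from \code{\link{classifyInteractions}}
#'   (or raw scores, in which case \code{cutoff} is applied first).
#' @param cutoff P-value cutoff used if \code{scores} lacks the
#'   \code{significant} column.
#' @param designs optional named list of \linkS4class{TargetDesign}; if
#'   given, \code{n_putative} counts every putative (host, target) pair in
#'   the designs, otherwise only scored pairs are counted.
#' @return data.frame per host: host, n_putative, n_significant, n_negative,
#'   mean_neglog_p (mean -log10 P over significant pairs, NA if none),
#'   pct_negative, call.
#' @export
classifyHosts <- function(scores, cutoff = 0.01, designs = NULL) {
  if (!("significant" %in% names(scores)))
    scores <- classifyInteractions(scores, cutoff)
  nPutative <- if (is.null(designs)) {
    table(scores$host)
  } else {
    table(unlist(lapply(designs, hostGenes)))
  }
  hosts <- sort(unique(c(scores$host, names(nPutative))))
  rows <- lapply(hosts, function(h) {
    s <- scores[scores$host == h, , drop = FALSE]
    nSig <- sum(s$significant)
    nNeg <- sum(s$negative)
    data.frame(
      host = h,
      n_putative = if (h %in% names(nPutative)) as.integer(nPutative[[h]])
                   else nrow(s),
      n_significant = nSig,
      n_negative = nNeg,
      mean_neglog_p = if (nSig) mean(-log10(s$p_real[s$significant]))
                      else NA_real_,
      pct_negative = if (nSig) 100 * nNeg / nSig else NA_real_,
      call = if (nSig == 0L) "uninformative"
             else if (nNeg > nSig - nNeg) "good_surrogate"
             else "bad_surrogate",
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Export the significant-negative interaction network
#'
#' Writes the predicted repressive network as a TSV edge list, one row per
#' (host, miRNA, target) edge: host-level calls are fanned back out to each
#' intronic miRNA of the host via the designs. Only significant negative
#' interactions are exported. Rows are ordered by host, target, miRNA so
#' identical inputs give byte-identical files.
#'
#' @param scores annotated data.frame from \code{\link{classifyInteractions}}.
#' @param designs named list of \linkS4class{TargetDesign}.
#' @param path output TSV (columns host, mirna, target, score, sign).
#' @return The exported data.frame, invisibly.
#' @export
exportNetwork <- function(scores, designs, path) {
  stopifnot(all(c("significant", "negative") %in% names(scores)))
  keep <- scores[scores$negative, , drop = FALSE]
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    design <- designs[[keep$target[i]]]
    if (is.null(design)) return(NULL)
    mirnas <- mirnaEdges(design)[[keep$host[i]]]
    if (is.null(mirnas)) return(NULL)
    data.frame(host = keep$host[i], mirna = mirnas, target = keep$target[i],
               score = keep$p_real[i], sign = keep$sign[i],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  net <- if (length(rows)) do.call(rbind, rows) else
    data.frame(host = character(), mirna = character(), target = character(),
               score = numeric(), sign = character(), stringsAsFactors = FALSE)
  net <- net[order(net$host, net$target, net$mirna), , drop = FALSE]
  rownames(net) <- NULL
  utils::write.table(net, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(net)
}
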