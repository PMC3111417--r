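#' Read an expression matrix from TSV
#'
#' Reads a tab-separated genes x samples matrix of linear-scale expression
#' intensities. The first header field names the gene-id column, the remaining
#' header fields are sample labels; each subsequent row is one gene. Empty
#' cells and the literal \code{NA} are treated as missing measurements and
#' are carried through so that \code{\link{filterGenes}} can drop the
#' affected genes. No transformation is applied: supply linear-scale (not
#' log-transformed) intensities, since the downstream model assumes miRNA
#' repression is additive in expression units.
#'
#' @param path path to the TSV file.
#' @param datasetId study label; defaults to the file name without extension.
#' @return An \linkS4class{ExpressionDataset} preserving row and column order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "A\t1\t2", "B\t3\t4"), tf)
#' ds <- readExpressionTSV(tf, "toy")
#' exprValues(ds)
#' @export
readExpressionTSV <- function(path,
                              datasetId = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("malformed expression TSV '", path, "': need a header and >= 1 gene row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("malformed header in '", path, "': no sample columns")
  samples <- header[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample labels in '", path, "': ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(header)))
    stop("row ", which(nf != length(header))[1L] + 1L, " of '", path,
         "' has ", nf[nf != length(header)][1L], " fields, expected ",
         length(header))
  genes <- vapply(rows, `[[`, "", 1L)
  if (any(!nzchar(genes)))
    stop("empty gene symbol at row ", which(!nzchar(genes))[1L] + 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene symbol in '", path, "': ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  cells <- vapply(rows, function(r) r[-1L], character(length(samples)))
  cells <- if (is.null(dim(cells))) matrix(cells, nrow = 1L) else t(cells)
  cells[cells == "" | cells == "NA"] <- NA_character_
  values <- suppressWarnings(array(as.numeric(cells), dim(cells)))
  bad <- is.na(values) & !is.na(cells)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric value '", cells[bad][1L], "' for gene ",
         genes[idx[1L]], ", sample ", samples[idx[2L]], " in '", path, "'")
  }
  dimnames(values) <- list(genes, samples)
  ExpressionDataset(values, datasetId)
}

#' Read a GEO GDS SOFT file as an expression matrix
#'
#' Minimal reader for the curated-GDS SOFT dialect: the block between
#' \code{!dataset_table_begin} and \code{!dataset_table_end} is parsed, probe
#' identifiers are mapped to gene symbols, and probes mapping to the same
#' symbol are collapsed. Only probes that map to a symbol are kept. The probe
#' map may be supplied as a two-column TSV (probe id, gene symbol) or be
#' omitted, in which case the table's \code{IDENTIFIER} column is used.
#' Cells equal to \code{null}, \code{NA} or empty are missing.
#'
#' Public repositories do not state how multi-probe genes should be
#' summarized; all three common policies are exposed and default to the
#' per-sample mean.
#'
#' @param path path to a SOFT-format GDS file.
#' @param datasetId study label; default from the file name.
#' @param probeMap optional path to a two-column probe-to-symbol TSV
#'   (no header), or a data.frame with columns probe and symbol.
#' @param collapse how to combine multiple probes of one symbol:
#'   "mean" (default), "first" (first probe in file order) or "max"
#'   (per-sample maximum).
#' @return An \linkS4class{ExpressionDataset}.
#' @export
readGeoSoft <- function(path, datasetId = sub("\\.[^.]*$", "", basename(path)),
                        probeMap = NULL,
                        collapse = c("mean", "first", "max")) {
  collapse <- match.arg(collapse)
  lines <- readLines(path)
  b <- grep("^!dataset_table_begin", lines)
  e <- grep("^!dataset_table_end", lines)
  if (length(b) != 1L || length(e) != 1L || e <= b + 1L)
    stop("no dataset table found in SOFT file '", path, "'")
  tab <- strsplit(lines[(b + 1L):(e - 1L)], "\t", fixed = TRUE)
  header <- tab[[1L]]
  idCol <- match("ID_REF", header)
  identCol <- match("IDENTIFIER", header)
  if (is.na(idCol)) stop("SOFT table lacks an ID_REF column")
  sampleCols <- grep("^GSM", header)
  if (!length(sampleCols)) stop("SOFT table lacks GSM sample columns")
  body <- tab[-1L]
  probes <- vapply(body, `[[`, "", idCol)
  symbols <- if (!is.null(probeMap)) {
    pm <- if (is.data.frame(probeMap)) probeMap else
      utils::read.delim(probeMap, header = FALSE,
                        col.names = c("probe", "symbol"),
                        colClasses = "character")
    pm$symbol[match(probes, pm$probe)]
  } else if (!is.na(identCol)) {
    vapply(body, `[[`, "", identCol)
  } else stop("no probe map supplied and no IDENTIFIER column present")
  symbols[symbols %in% c("", "--Control", "null", "NA")] <- NA_character_
  vals <- t(vapply(body, function(r) {
    x <- r[sampleCols]
    x[x %in% c("", "null", "NA")] <- NA_character_
    suppressWarnings(as.numeric(x))
  }, numeric(length(sampleCols))))
  keep <- !is.na(symbols)
  if (!any(keep)) stop("no probe could be mapped to a gene symbol")
  vals <- vals[keep, , drop = FALSE]
  symbols <- symbols[keep]
  collapsed <- switch(collapse,
    first = vals[!duplicated(symbols), , drop = FALSE],
    mean = do.call(rbind, lapply(split(seq_along(symbols), symbols)[
      unique(symbols)], function(i) colMeans(vals[i, , drop = FALSE],
                                             na.rm = FALSE))),
    max = do.call(rbind, lapply(split(seq_along(symbols), symbols)[
      unique(symbols)], function(i) apply(vals[i, , drop = FALSE], 2L, max))))
  rownames(collapsed) <- unique(symbols)
  colnames(collapsed) <- header[sampleCols]
  ExpressionDataset(collapsed, datasetId)
}

#' Filter uninformative genes
#'
#' Removes genes with any missing value, then genes whose maximum absolute
#' expression across samples falls strictly below the given percentile of the
#' per-gene maximum-absolute-value distribution (the low-signal filter of the
#' MATLAB \code{genelowvalfilter} convention). The percentile is computed
#' with linear interpolation between order statistics; genes tied with the
#' threshold are kept. Survivor order is preserved.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param percentile fraction in [0, 1]; default 0.10.
#' @return A filtered \linkS4class{ExpressionDataset}.
#' @export
filterGenes <- function(ds, percentile = 0.10) {
  stopifnot(is(ds, "ExpressionDataset"))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile < 0 || percentile > 1)
    stop("'percentile' must be a single value in [0, 1]")
  m <- exprValues(ds)
  complete <- rowSums(is.na(m)) == 0L
  m <- m[complete, , drop = FALSE]
  if (!nrow(m))
    stop("all genes removed: every gene of '", datasetId(ds),
         "' has missing values")
  mx <- apply(abs(m), 1L, max)
  thr <- stats::quantile(mx, percentile, names = FALSE, type = 7)
  keep <- mx >= thr
  if (!any(keep))
    stop("all genes removed by the low-signal filter in '", datasetId(ds), "'")
  ExpressionDataset(m[keep, , drop = FALSE], datasetId(ds))
}

#' Per-sample down-regulation vector of a gene
#'
#' The response of the linear model: for each sample, the mean expression
#' over all genes of the (filtered) dataset minus the gene's measured
#' expression. A positive entry means the gene is expressed below the
#' dataset-wide mean in that sample, i.e. is down-regulated there. Summed
#' over the whole gene universe the vector is zero at every sample.
#'
#' @param ds a filtered \linkS4class{ExpressionDataset} (no missing values).
#' @param geneId gene symbol present in \code{ds}.
#' @return Named numeric vector (one entry per sample).
#' @examples
#' m <- matrix(c(1, 3, 3, 5), 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' computeDownregulation(ExpressionDataset(m, "toy"), "g1")  # c(1, 1)
#' @export
computeDownregulation <- function(ds, geneId) {
  stopifnot(is(ds, "ExpressionDataset"))
  m <- exprValues(ds)
  if (!(geneId %in% rownames(m)))
    stop("gene '", geneId, "' not present in dataset '", datasetId(ds), "'")
  if (anyNA(m))
    stop("dataset '", datasetId(ds),
         "' contains missing values; apply filterGenes() first")
  colMeans(m) - m[geneId, ]
}

#' Unit-norm host expression profile
#'
#' Extracts a host gene's expression row and rescales it to unit Euclidean
#' length, the form in which host profiles enter the regression design.
#' A host absent from the dataset raises a condition of class
#' \code{intromiR_missing_host} so callers can mask the column for that
#' dataset (as when a host's probe set is absent from a platform).
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param hostGeneId host gene symbol.
#' @return Named numeric unit vector over samples.
#' @export
normalizeHostProfile <- function(ds, hostGeneId) {
  stopifnot(is(ds, "ExpressionDataset"))
  m <- exprValues(ds)
  if (!(hostGeneId %in% rownames(m))) {
    cond <- structure(
      class = c("intromiR_missing_host", "error", "condition"),
      list(message = paste0("host gene '", hostGeneId,
                            "' absent from dataset '", datasetId(ds), "'"),
           call = sys.call()))
    stop(cond)
  }
  x <- m[hostGeneId, ]
  if (anyNA(x))
    stop("host '", hostGeneId, "' has missing values in '", datasetId(ds), "'")
  nrm <- sqrt(sum(x^2))
  if (nrm == 0)
    stop("degenerate host profile: '", hostGeneId, "' is all-zero in '",
         datasetId(ds), "'")
  x / nrm
}

# all unit-norm host profiles present in a dataset, as an S x H matrix
.hostProfileMatrix <- function(ds, hosts) {
  m <- exprValues(ds)
  present <- hosts[hosts %in% rownames(m)]
  if (!length(present)) return(NULL)
  X <- t(m[present, , drop = FALSE])
  nrm <- sqrt(colSums(X^2))
  ok <- nrm > 0
  X <- sweep(X[, ok, drop = FALSE], 2L, nrm[ok], "/")
  if (!ncol(X)) NULL else X
}
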