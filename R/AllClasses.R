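#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay
NULL

#' ExpressionDataset: one study's expression matrix
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' genes x samples matrix of linear-scale expression intensities for one
#' study, together with a dataset identifier. Rows are gene symbols (unique),
#' columns are sample labels. Values must be real; \code{NA} marks missing
#' measurements and is only tolerated before \code{\link{filterGenes}} has
#' been applied. Expression is expected on the linear scale: the downstream
#' model is additive in expression units, so log-transformed input will
#' misestimate regulatory weights.
#'
#' @slot datasetId single character label for the study (e.g. a GDS accession).
#'
#' @seealso \code{\link{readExpressionTSV}}, \code{\link{filterGenes}},
#'   \code{\link{computeDownregulation}}
#' @export
setClass("ExpressionDataset",
  contains = "SummarizedExperiment",
  slots = c(datasetId = "character")
)

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (length(object@datasetId) != 1L || is.na(object@datasetId) ||
      !nzchar(object@datasetId))
    msg <- c(msg, "'datasetId' must be a single non-empty string")
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'exprs' is missing")
  else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(m))
      msg <- c(msg, "expression values must be numeric")
    if (any(is.nan(m)) || any(is.infinite(m)))
      msg <- c(msg, "expression values must be finite (NaN/Inf found)")
    rn <- rownames(m)
    if (is.null(rn) || anyNA(rn) || !all(nzchar(rn)))
      msg <- c(msg, "all genes must have non-empty symbols")
    else if (anyDuplicated(rn))
      msg <- c(msg, paste0("duplicate gene symbols: ",
                           paste(unique(rn[duplicated(rn)]), collapse = ", ")))
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
      msg <- c(msg, "sample labels must be present and unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix (genes x samples) with unique non-empty
#'   rownames (gene symbols) and unique colnames (sample labels).
#' @param datasetId single character study label.
#' @return An \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' ExpressionDataset(m, "toy")
#' @export
ExpressionDataset <- function(values, datasetId) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = list(exprs = values))
  new("ExpressionDataset", se, datasetId = as.character(datasetId))
}

#' TargetDesign: candidate host regressors for one target gene
#'
#' The design of the per-target multi-regulator model after collapsing the
#' host / intronic-miRNA / target DAG: each distinct host gene whose intronic
#' miRNA(s) putatively target the gene contributes exactly one regressor
#' column. Hosts of duplicated miRNAs keep separate columns; several miRNAs in
#' one host collapse onto one column whose score is later fanned back out to
#' each miRNA (\code{\link{fanoutToMirnas}}). Column order is lexicographic by
#' host symbol so weight vectors align across datasets.
#'
#' @slot targetGene the target gene symbol.
#' @slot hostGenes ordered (lexicographic) distinct host gene symbols.
#' @slot mirnaEdges named list, one entry per host, of the miRNA ids whose
#'   putative targeting of \code{targetGene} drives the host's inclusion.
#' @seealso \code{\link{buildDesign}}
#' @export
setClass("TargetDesign",
  slots = c(targetGene = "character",
            hostGenes = "character",
            mirnaEdges = "list")
)

setValidity("TargetDesign", function(object) {
  msg <- character()
  if (length(object@targetGene) != 1L || !nzchar(object@targetGene))
    msg <- c(msg, "'targetGene' must be a single non-empty string")
  if (length(object@hostGenes) < 1L)
    msg <- c(msg, "a design needs at least one host gene")
  if (anyDuplicated(object@hostGenes))
    msg <- c(msg, "'hostGenes' must be distinct")
  if (is.unsorted(object@hostGenes))
    msg <- c(msg, "'hostGenes' must be in lexicographic order")
  if (!identical(names(object@mirnaEdges), object@hostGenes))
    msg <- c(msg, "'mirnaEdges' must be named by hostGenes, in order")
  if (any(!vapply(object@mirnaEdges, length, 1L)))
    msg <- c(msg, "every host must trace to at least one miRNA edge")
  if (length(msg)) msg else TRUE
})

#' NullPool: the pooled empirical permutation null
#'
#' Holds the L1-rescaled regression weights obtained by refitting every
#' (target, dataset) model after permuting the host-gene labels. The pooled
#' weights are the empirical null distribution against which both the real
#' (P) and the permuted-control (Q) per-pair weight samples are ranked; the
#' per-pair permuted samples are retained for the Q computation.
#'
#' @slot method one of "ULM", "CLM", "CORR".
#' @slot pool numeric vector of all non-degenerate permuted rescaled weights.
#' @slot permWeights data.frame (dataset, target, host, perm, rescaled): the
#'   permuted weights indexed by the original (pre-permutation) host label.
#' @slot nPerms permutations per (target, dataset).
#' @slot seed the RNG seed used (NA if the caller managed the RNG).
#' @slot scope "universe" or "design" host-relabelling scope.
#' @seealso \code{\link{buildNullPool}}, \code{\link{scoreInteractions}}
#' @export
setClass("NullPool",
  slots = c(method = "character", pool = "numeric",
            permWeights = "data.frame", nPerms = "integer",
            seed = "integer", scope = "character")
)

setValidity("NullPool", function(object) {
  msg <- character()
  if (!object@method %in% c("ULM", "CLM", "CORR"))
    msg <- c(msg, "unknown method")
  if (length(object@pool) == 0L)
    msg <- c(msg, "null pool is empty")
  if (length(object@pool) != nrow(object@permWeights))
    msg <- c(msg, "pool size must equal the number of retained permuted weights")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: conditions for a synthetic compendium
#'
#' Bundles every knob of the synthetic-compendium generator; see
#' \code{\link{simulationConfig}} for the constructor, defaults and the
#' meaning of each condition.
#'
#' @export
setClass("SimulationConfig",
  slots = c(nDatasets = "integer", nSamples = "integer", nHosts = "integer",
            nTargets = "integer", nDecoys = "integer",
            edgesPerTarget = "integer", edges = "ANY",
            noiseSd = "numeric", effectSize = "numeric",
            hostCor = "numeric", confounderSd = "numeric",
            hostScale = "numeric", nBackground = "integer",
            baselineRange = "numeric", bgSdRange = "numeric",
            scenarios = "character", mirnasPerHost = "integer",
            decoupleImpact = "numeric", sharedMirWeight = "numeric",
            seed = "integer")
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pos <- c(nDatasets = object@nDatasets, nSamples = object@nSamples,
           nHosts = object@nHosts, nTargets = object@nTargets,
           mirnasPerHost = object@mirnasPerHost)
  if (any(pos < 1L))
    msg <- c(msg, "all counts must be positive")
  if (object@nDecoys < 0L || object@edgesPerTarget < 0L)
    msg <- c(msg, "'nDecoys' and 'edgesPerTarget' must be >= 0")
  if (object@noiseSd < 0)
    msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@hostCor < 0 || object@hostCor >= 1)
    msg <- c(msg, "'hostCor' must be in [0, 1)")
  if (object@edgesPerTarget + object@nDecoys > object@nHosts)
    msg <- c(msg, "more regulators + decoys per design than hosts")
  if (length(object@scenarios) != object@nHosts)
    msg <- c(msg, "'scenarios' must have one entry per host")
  if (!all(object@scenarios %in%
           c("coupled", "independent_promoter", "mirna_targeted_host")))
    msg <- c(msg, "unknown scenario label")
  if (!is.null(object@edges)) {
    e <- object@edges
    if (!is.data.frame(e) || !all(c("host", "target", "w") %in% names(e)))
      msg <- c(msg, "'edges' must be a data.frame with host, target, w")
    else {
      hosts <- sprintf("HOST%02d", seq_len(object@nHosts))
      targets <- sprintf("TG%02d", seq_len(object@nTargets))
      if (!all(e$host %in% hosts) || !all(e$target %in% targets))
        msg <- c(msg, "'edges' references unknown host or target ids")
      if (any(e$w <= 0))
        msg <- c(msg, "planted effect sizes must be > 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted structure of a synthetic compendium
#'
#' @slot edges data.frame (host, target, w) of planted repressive edges.
#' @slot scenarios named character vector, per host, of the surrogacy
#'   scenario: "coupled", "independent_promoter" or "mirna_targeted_host".
#' @seealso \code{\link{simulateCompendium}}, \code{\link{evaluateRecovery}}
#' @export
setClass("GroundTruth",
  slots = c(edges = "data.frame", scenarios = "character"))
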