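#' @rdname ExpressionDataset-class
#' @param object,x an \linkS4class{ExpressionDataset}.
#' @export
setGeneric("datasetId", function(object) standardGeneric("datasetId"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("datasetId", "ExpressionDataset", function(object) object@datasetId)

#' @rdname ExpressionDataset-class
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("exprValues", "ExpressionDataset",
          function(object) SummarizedExperiment::assay(object, "exprs"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("geneIds", "ExpressionDataset", function(object) rownames(object))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("sampleIds", "ExpressionDataset", function(object) colnames(object))

setMethod("show", "ExpressionDataset", function(object) {
  cat("ExpressionDataset '", object@datasetId, "': ",
      nrow(object), " genes x ", ncol(object), " samples\n", sep = "")
  m <- exprValues(object)
  if (anyNA(m)) cat("  (contains missing values; run filterGenes())\n")
})

#' @rdname TargetDesign-class
#' @param object a \linkS4class{TargetDesign}.
#' @export
setGeneric("targetGene", function(object) standardGeneric("targetGene"))

#' @rdname TargetDesign-class
#' @export
setMethod("targetGene", "TargetDesign", function(object) object@targetGene)

#' @rdname TargetDesign-class
#' @export
setGeneric("hostGenes", function(object) standardGeneric("hostGenes"))

#' @rdname TargetDesign-class
#' @export
setMethod("hostGenes", "TargetDesign", function(object) object@hostGenes)

#' @rdname TargetDesign-class
#' @export
setGeneric("mirnaEdges", function(object) standardGeneric("mirnaEdges"))

#' @rdname TargetDesign-class
#' @export
setMethod("mirnaEdges", "TargetDesign", function(object) object@mirnaEdges)

setMethod("show", "TargetDesign", function(object) {
  cat("TargetDesign for", object@targetGene, "with",
      length(object@hostGenes), "host regressor(s):\n")
  for (h in object@hostGenes)
    cat("  ", h, " <- [", paste(object@mirnaEdges[[h]], collapse = ", "),
        "]\n", sep = "")
})

#' @rdname NullPool-class
#' @param object a \linkS4class{NullPool}.
#' @export
setGeneric("nullWeights", function(object) standardGeneric("nullWeights"))

#' @rdname NullPool-class
#' @export
setMethod("nullWeights", "NullPool", function(object) object@pool)

setMethod("show", "NullPool", function(object) {
  cat("NullPool (", object@method, "): ", length(object@pool),
      " pooled permuted weights, ", object@nPerms, " perm(s)/dataset, scope '",
      object@scope, "'\n", sep = "")
  cat("  mean ", signif(mean(object@pool), 4),
      ", sd ", signif(stats::sd(object@pool), 4), "\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nDatasets, "datasets x", object@nSamples,
      "samples;", object@nHosts, "hosts,", object@nTargets, "targets,",
      object@nBackground, "background genes\n")
  cat("  edges/target", object@edgesPerTarget, "(w* =",
      paste(unique(object@effectSize), collapse = "/"),
      "), decoys", object@nDecoys, ", noise sd", object@noiseSd,
      ", host cor", object@hostCor, ", confounder sd",
      object@confounderSd, "\n")
  cat("  scenarios:", paste(names(table(object@scenarios)),
      table(object@scenarios), sep = ":", collapse = " "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@edges), "planted edges over",
      length(object@scenarios), "hosts\n")
})

#' @rdname GroundTruth-class
#' @param object a \linkS4class{GroundTruth}.
#' @export
setGeneric("plantedEdges", function(object) standardGeneric("plantedEdges"))

#' @rdname GroundTruth-class
#' @export
setMethod("plantedEdges", "GroundTruth", function(object) object@edges)

#' @rdname GroundTruth-class
#' @export
setGeneric("hostScenarios", function(object) standardGeneric("hostScenarios"))

#' @rdname GroundTruth-class
#' @export
setMethod("hostScenarios", "GroundTruth", function(object) object@scenarios)
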