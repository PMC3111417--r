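#' Run the full target-prediction pipeline
#'
#' Orchestrates every stage in order: read (or simulate) the expression
#' compendium, filter genes, build per-target host designs, fit per-dataset
#' weights (real and host-permuted), score each host-target pair against the
#' pooled permutation null (P and Q), choose the significance cutoff, flag
#' significant negative interactions, classify hosts as good or bad
#' surrogates, and (optionally) write all result tables plus a JSON run
#' summary.
#'
#' Exactly one input source must be given: either \code{expressionPaths} +
#' \code{hostMapPath} + \code{targetMapPath}, or \code{simConfig}. The fixed
#' cutoff P <= 0.01 is the default; setting \code{rocSpecificity} switches to
#' the ROC-chosen cutoff at that specificity. With an \code{outputDir}, per
#' method the files \code{weights_<m>.tsv}, \code{scores_<m>.tsv},
#' \code{network_<m>.tsv} and \code{surrogacy_<m>.tsv} are written, plus one
#' \code{summary.json}; identical inputs and seed give byte-identical
#' outputs. On any stage failure the partial outputs are removed.
#'
#' @param expressionPaths character vector of expression TSV paths.
#' @param hostMapPath,targetMapPath annotation TSV paths
#'   (see \code{\link{readHostMap}}, \code{\link{readTargetMap}}).
#' @param simConfig a \linkS4class{SimulationConfig} instead of file input.
#' @param methods any of "ULM", "CLM", "CORR" (may be several).
#' @param cutoff fixed P-value cutoff (default 0.01).
#' @param rocSpecificity if non-NULL, choose the cutoff by ROC at this
#'   specificity instead of the fixed value.
#' @param nPerms permutations per (target, dataset) for the null pool.
#' @param seed integer seed for the permutation RNG (and, for simulated
#'   input, the compendium unless the config carries its own seed).
#' @param filterPercentile low-signal filter percentile
#'   (see \code{\link{filterGenes}}).
#' @param scope host permutation scope (see \code{\link{permuteHosts}}).
#' @param outputDir optional output directory.
#' @return List with per-method elements: \code{weights}, \code{scores}
#'   (annotated), \code{report}, \code{cutoff}; plus \code{designs},
#'   \code{truth} (for simulated input) and \code{summary}.
#' @export
runPipeline <- function(expressionPaths = NULL, hostMapPath = NULL,
                        targetMapPath = NULL, simConfig = NULL,
                        methods = "ULM", cutoff = 0.01,
                        rocSpecificity = NULL, nPerms = 1L, seed = 1L,
                        filterPercentile = 0.10,
                        scope = c("universe", "design"), outputDir = NULL) {
  scope <- match.arg(scope)
  methods <- match.arg(methods, c("ULM", "CLM", "CORR"), several.ok = TRUE)
  fromFiles <- !is.null(expressionPaths)
  if (fromFiles == !is.null(simConfig))
    stop("config error: supply exactly one input source ",
         "(expressionPaths or simConfig)")
  if (fromFiles) {
    if (is.null(hostMapPath))
      stop("config error: 'hostMapPath' is missing")
    if (is.null(targetMapPath))
      stop("config error: 'targetMapPath' is missing")
  }
  written <- character()
  emit <- function(obj, name) {
    if (is.null(outputDir)) return(invisible(NULL))
    path <- file.path(outputDir, name)
    written <<- c(written, path)
    if (is.data.frame(obj))
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA)
    invisible(path)
  }
  if (!is.null(outputDir))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)

  run <- function() {
    truth <- NULL
    if (fromFiles) {
      datasets <- lapply(expressionPaths, readExpressionTSV)
      hostMap <- readHostMap(hostMapPath)
      targetMap <- readTargetMap(targetMapPath)
    } else {
      sim <- simulateCompendium(simConfig)
      datasets <- sim$datasets
      hostMap <- sim$hostMap
      targetMap <- sim$targetMap
      truth <- sim$truth
    }
    datasets <- lapply(datasets, filterGenes, percentile = filterPercentile)
    designs <- buildDesigns(hostMap, targetMap)
    if (!length(designs)) stop("data error: no target with a usable design")
    out <- list(designs = designs, truth = truth)
    summary <- list(seed = seed, nPerms = nPerms, scope = scope,
                    nDatasets = length(datasets), nTargets = length(designs),
                    filterPercentile = filterPercentile, methods = list())
    for (i in seq_along(methods)) {
      m <- methods[i]
      wt <- fitWeightTable(datasets, designs, m)
      if (!nrow(wt)) stop("data error: no non-degenerate fit for ", m)
      pool <- buildNullPool(datasets, designs, m, nPerms = nPerms,
                            seed = seed + 7919L * i, scope = scope)
      scores <- scoreInteractions(wt, pool)
      cut <- if (is.null(rocSpecificity)) cutoff else
        chooseCutoff(buildRoc(scores$p_real, scores$p_perm), rocSpecificity)
      scores <- classifyInteractions(scores, cut)
      report <- classifyHosts(scores, cut, designs = designs)
      emit(wt, paste0("weights_", m, ".tsv"))
      emit(scores, paste0("scores_", m, ".tsv"))
      emit(report, paste0("surrogacy_", m, ".tsv"))
      net <- if (is.null(outputDir)) {
        tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
        exportNetwork(scores, designs, tmp)
      } else {
        netPath <- file.path(outputDir, paste0("network_", m, ".tsv"))
        written <<- c(written, netPath)
        exportNetwork(scores, designs, netPath)
      }
      out[[m]] <- list(weights = wt, scores = scores, report = report,
                       network = net, cutoff = as.numeric(cut),
                       poolSize = length(nullWeights(pool)))
      summary$methods[[m]] <- list(
        cutoff = as.numeric(cut), poolSize = length(nullWeights(pool)),
        nPairs = nrow(scores), nSignificant = sum(scores$significant),
        nNegative = sum(scores$negative),
        goodSurrogates = sum(report$call == "good_surrogate"),
        badSurrogates = sum(report$call == "bad_surrogate"),
        uninformative = sum(report$call == "uninformative"))
    }
    out$summary <- summary
    emit(summary, "summary.json")
    out
  }
  tryCatch(run(), error = function(e) {
    if (length(written)) unlink(written)
    stop(e)
  })
}
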