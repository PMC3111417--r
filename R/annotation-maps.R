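#' Read a miRNA-to-host-gene association table
#'
#' Two-column TSV with header \code{mirna_id<TAB>host_gene_symbol}, one row
#' per intronic miRNA / host gene association. A miRNA duplicated in several
#' genomic loci may appear under multiple hosts, and a host may carry several
#' intronic miRNAs. Exact duplicate rows are collapsed.
#'
#' @param path path to the TSV file.
#' @return data.frame with character columns \code{mirna} and \code{host}.
#' @export
readHostMap <- function(path) {
  .readPairTSV(path, c("mirna", "host"))
}

#' Read a putative miRNA-to-target table
#'
#' Two-column TSV with header \code{mirna_id<TAB>target_gene_symbol}, one row
#' per sequence-predicted miRNA/target pair (e.g. TargetScan-style
#' predictions). Duplicate rows are collapsed. The (miRNA, target) relation
#' is treated as binary: multiple 3'UTR sites do not weight a pair more.
#'
#' @param path path to the TSV file.
#' @return data.frame with character columns \code{mirna} and \code{target}.
#' @export
readTargetMap <- function(path) {
  .readPairTSV(path, c("mirna", "target"))
}

.readPairTSV <- function(path, cols) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("empty annotation table: '", path, "'")
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 2L)
  if (length(bad))
    stop("malformed row ", bad[1L] + 1L, " in '", path,
         "': expected 2 tab-separated fields")
  df <- data.frame(vapply(rows, `[[`, "", 1L), vapply(rows, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  names(df) <- cols
  if (any(!nzchar(df[[1L]])) || any(!nzchar(df[[2L]])))
    stop("empty identifier at row ",
         which(!nzchar(df[[1L]]) | !nzchar(df[[2L]]))[1L] + 1L,
         " in '", path, "'")
  unique(df)
}

#' Build the host-gene design for one target
#'
#' Collapses the host / intronic-miRNA / target DAG into the direct
#' host-to-target design that is actually fitted: the putative miRNA
#' regulators of the target are looked up, mapped to their host genes, and
#' each distinct host becomes one regressor column. A miRNA duplicated in two
#' hosts yields two columns (hosts of duplicated miRNAs get separate
#' weights); several miRNAs in one host collapse to one column. miRNAs in
#' the target map that do not resolve to any host are dropped with a message.
#'
#' @param targetGeneId the target gene symbol.
#' @param hostMap data.frame from \code{\link{readHostMap}}.
#' @param targetMap data.frame from \code{\link{readTargetMap}}.
#' @return A \linkS4class{TargetDesign}, or \code{NULL} (with a message) if
#'   the target has no resolvable putative regulator.
#' @examples
#' hm <- data.frame(mirna = c("miR-1", "miR-2"), host = c("H1", "H1"))
#' tm <- data.frame(mirna = c("miR-1", "miR-2"), target = c("G", "G"))
#' buildDesign("G", hm, tm)  # one host column with two miRNA edges
#' @export
buildDesign <- function(targetGeneId, hostMap, targetMap) {
  stopifnot(all(c("mirna", "host") %in% names(hostMap)),
            all(c("mirna", "target") %in% names(targetMap)))
  mirnas <- unique(targetMap$mirna[targetMap$target == targetGeneId])
  if (!length(mirnas)) {
    message("target '", targetGeneId, "' has no putative miRNA regulator; skipped")
    return(NULL)
  }
  unresolved <- setdiff(mirnas, hostMap$mirna)
  if (length(unresolved)) {
    message("dropping ", length(unresolved), " miRNA(s) with no host for '",
            targetGeneId, "': ", paste(unresolved, collapse = ", "))
    mirnas <- setdiff(mirnas, unresolved)
  }
  if (!length(mirnas)) {
    message("target '", targetGeneId, "' has no resolvable regulator; skipped")
    return(NULL)
  }
  hm <- hostMap[hostMap$mirna %in% mirnas, , drop = FALSE]
  hosts <- sort(unique(hm$host))
  edges <- lapply(hosts, function(h) sort(unique(hm$mirna[hm$host == h])))
  names(edges) <- hosts
  new("TargetDesign", targetGene = targetGeneId, hostGenes = hosts,
      mirnaEdges = edges)
}

#' Build designs for all targets of a target map
#'
#' @param hostMap,targetMap as in \code{\link{buildDesign}}.
#' @param targets targets to build; defaults to all targets in the map.
#' @return Named list of \linkS4class{TargetDesign} (targets without
#'   resolvable regulators are omitted).
#' @export
buildDesigns <- function(hostMap, targetMap,
                         targets = sort(unique(targetMap$target))) {
  designs <- lapply(targets, buildDesign, hostMap = hostMap,
                    targetMap = targetMap)
  names(designs) <- targets
  designs[!vapply(designs, is.null, TRUE)]
}

#' Fan a per-host result back out to miRNAs
#'
#' Host-level scores are computed once per host column; this expands them to
#' one row per (miRNA, host) edge of the design, copying the host's result
#' to each of its intronic miRNAs.
#'
#' @param design a \linkS4class{TargetDesign}.
#' @param hostResults named vector (or one-column named list) of per-host
#'   results; names must cover the design's hosts.
#' @return data.frame (mirna, target, host, result); empty if the design has
#'   no hosts with results.
#' @export
fanoutToMirnas <- function(design, hostResults) {
  stopifnot(is(design, "TargetDesign"))
  hosts <- intersect(design@hostGenes, names(hostResults))
  rows <- lapply(hosts, function(h)
    data.frame(mirna = design@mirnaEdges[[h]], target = design@targetGene,
               host = h, result = unname(hostResults[[h]]),
               stringsAsFactors = FALSE))
  if (!length(rows))
    return(data.frame(mirna = character(), target = character(),
                      host = character(), result = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
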