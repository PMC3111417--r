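#' Configure a synthetic expression compendium
#'
#' Defines the conditions of a simulated multi-study compendium with known
#' ground truth, emulating the situation the predictor faces in real data:
#' many independent datasets; host genes whose unit-norm expression profiles
#' drive planted repressive edges on target genes; putative-but-nonfunctional
#' decoy hosts in every design (sequence-based target predictions have
#' substantial false-positive rates); co-expression structure among hosts;
#' and a dataset-wide expression program that confounds simple correlations.
#'
#' Host transcription profiles are i.i.d. Gaussian vectors, unit-normalized
#' and scaled to amplitude \code{hostScale}; they load (with balanced signs)
#' on a per-dataset shared program so that hosts fall into two
#' anti-correlated co-expression modules with pairwise correlation about
#' \code{hostCor}. Planted edges for each target draw hosts from both
#' modules (combinatorial regulation across programs). Each target also
#' loads the shared program with a per-dataset N(0, \code{confounderSd})
#' coefficient -- program variation unrelated to miRNA action, typically the
#' dominant variance component of real expression data. Targets are emitted
#' on the linear scale as baseline minus the planted regulator contributions
#' plus spherical Gaussian noise; background genes fill out the universe so
#' that per-sample means (the reference for down-regulation vectors) behave
#' like a genome-scale dataset.
#'
#' Per-host surrogacy scenarios: \code{"coupled"} hosts are emitted exactly
#' as the regulator profile their miRNA follows (host mRNA is a perfect
#' surrogate); \code{"independent_promoter"} hosts regulate their targets
#' through a latent profile uncorrelated with the emitted host mRNA (the
#' miRNA has its own promoter); \code{"mirna_targeted_host"} hosts are
#' co-transcribed with their miRNA but the emitted host mRNA is degraded by
#' another miRNA (\code{decoupleImpact} units) which also represses the
#' host's targets (\code{sharedMirWeight}), the shared-regulation confound
#' that makes such hosts appear positively co-expressed with their targets.
#'
#' @param nDatasets,nSamples number of studies and samples per study.
#' @param nHosts,nTargets,nBackground genes of each class per study.
#' @param edgesPerTarget planted regulators per target (ignored when
#'   \code{edges} is supplied).
#' @param nDecoys non-regulating hosts added to each design.
#' @param noiseSd sd of the spherical Gaussian noise on targets.
#' @param effectSize planted weight w* (recycled over edges).
#' @param hostCor within-module host-host correlation (0 <= r < 1).
#' @param confounderSd sd of the per-target, per-dataset program loading.
#' @param hostScale amplitude of emitted host rows (they are unit profiles
#'   times this scale; large enough to pass the low-signal filter).
#' @param baselineRange,bgSdRange uniform ranges for background-gene
#'   baselines and noise sds; targets sit at the centre of
#'   \code{baselineRange}.
#' @param scenarios character vector (length \code{nHosts}) of per-host
#'   scenarios; default all \code{"coupled"}.
#' @param mirnasPerHost intronic miRNAs annotated per host.
#' @param decoupleImpact,sharedMirWeight see Details.
#' @param edges optional explicit planted edge list (data.frame host,
#'   target, w) overriding the sampler.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nDatasets = 50L, nSamples = 30L, nHosts = 12L,
                             nTargets = 20L, edgesPerTarget = 3L,
                             nDecoys = 3L, noiseSd = 0.5, effectSize = 1,
                             hostCor = 0.5, confounderSd = 4,
                             hostScale = 30, nBackground = 1000L,
                             baselineRange = c(8, 12), bgSdRange = c(0.3, 1.5),
                             scenarios = rep("coupled", nHosts),
                             mirnasPerHost = 1L, decoupleImpact = 1.5,
                             sharedMirWeight = 1, edges = NULL, seed = 1L) {
  new("SimulationConfig",
      nDatasets = as.integer(nDatasets), nSamples = as.integer(nSamples),
      nHosts = as.integer(nHosts), nTargets = as.integer(nTargets),
      nDecoys = as.integer(nDecoys),
      edgesPerTarget = as.integer(edgesPerTarget), edges = edges,
      noiseSd = noiseSd, effectSize = effectSize, hostCor = hostCor,
      confounderSd = confounderSd, hostScale = hostScale,
      nBackground = as.integer(nBackground), baselineRange = baselineRange,
      bgSdRange = bgSdRange, scenarios = scenarios,
      mirnasPerHost = as.integer(mirnasPerHost),
      decoupleImpact = decoupleImpact, sharedMirWeight = sharedMirWeight,
      seed = as.integer(seed))
}

.unit <- function(v) v / sqrt(sum(v^2))

# sample planted edges: each target gets regulators from both co-expression
# modules (majority from one, one from the other) so that combinatorial
# regulation spans programs
.sampleEdges <- function(targets, hosts, moduleSign, edgesPerTarget, wStar) {
  if (edgesPerTarget == 0L)
    return(data.frame(host = character(), target = character(), w = numeric(),
                      stringsAsFactors = FALSE))
  wStar <- rep_len(wStar, length(targets) * edgesPerTarget)
  i <- 0L
  do.call(rbind, lapply(targets, function(tg) {
    pa <- hosts[moduleSign > 0]; pb <- hosts[moduleSign < 0]
    if (stats::runif(1) < 0.5) { tmp <- pa; pa <- pb; pb <- tmp }
    nMaj <- min(edgesPerTarget - 1L, length(pa))
    nMin <- min(edgesPerTarget - nMaj, length(pb))
    h <- c(sample(pa, nMaj), sample(pb, nMin))
    if (length(h) < edgesPerTarget)
      h <- c(h, sample(setdiff(hosts, h), edgesPerTarget - length(h)))
    w <- wStar[i + seq_along(h)]; i <<- i + length(h)
    data.frame(host = h, target = tg, w = w, stringsAsFactors = FALSE)
  }))
}

#' Simulate a multi-dataset compendium with planted regulation
#'
#' Generates expression datasets, the miRNA-to-host and putative
#' miRNA-to-target annotation tables, and the ground truth, under the
#' conditions of a \linkS4class{SimulationConfig}. The putative target map
#' contains the planted edges plus \code{nDecoys} non-regulating hosts per
#' target, so the emitted files exercise exactly the interfaces the readers
#' consume. All randomness flows through R's RNG, seeded from the config:
#' the same config yields an identical compendium.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return List with elements \code{datasets} (list of
#'   \linkS4class{ExpressionDataset}), \code{hostMap}, \code{targetMap}
#'   (data.frames as returned by the readers) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @examples
#' sim <- simulateCompendium(simulationConfig(nDatasets = 2, nSamples = 10,
#'   nHosts = 4, nTargets = 3, nBackground = 50, edgesPerTarget = 2,
#'   nDecoys = 1, seed = 7))
#' length(sim$datasets)
#' plantedEdges(sim$truth)
#' @export
simulateCompendium <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  S <- cfg@nSamples
  hosts <- sprintf("HOST%02d", seq_len(cfg@nHosts))
  targets <- sprintf("TG%02d", seq_len(cfg@nTargets))
  scenarios <- cfg@scenarios
  names(scenarios) <- hosts

  # balanced module membership, shuffled
  moduleSign <- rep(c(-1, 1), length.out = cfg@nHosts)[sample(cfg@nHosts)]
  names(moduleSign) <- hosts

  edges <- if (!is.null(cfg@edges)) cfg@edges else
    .sampleEdges(targets, hosts, moduleSign, cfg@edgesPerTarget,
                 cfg@effectSize)

  # annotation tables: miRNAs per host, putative targets = planted + decoys
  mirnaOf <- lapply(hosts, function(h) {
    idx <- match(h, hosts)
    sprintf("miR-s%02d%s", idx, letters[seq_len(cfg@mirnasPerHost)])
  })
  names(mirnaOf) <- hosts
  hostMap <- data.frame(mirna = unlist(mirnaOf),
                        host = rep(hosts, each = cfg@mirnasPerHost),
                        stringsAsFactors = FALSE)
  putative <- do.call(rbind, lapply(targets, function(tg) {
    ph <- edges$host[edges$target == tg]
    nd <- min(cfg@nDecoys, cfg@nHosts - length(ph))
    dec <- if (nd > 0L) sample(setdiff(hosts, ph), nd) else character()
    data.frame(host = c(ph, dec), target = tg, stringsAsFactors = FALSE)
  }))
  targetMap <- unique(do.call(rbind, lapply(seq_len(nrow(putative)),
    function(i) data.frame(mirna = mirnaOf[[putative$host[i]]],
                           target = putative$target[i],
                           stringsAsFactors = FALSE))))

  rho <- cfg@hostCor
  baseT <- mean(cfg@baselineRange)
  datasets <- vector("list", cfg@nDatasets)
  for (k in seq_len(cfg@nDatasets)) {
    zraw <- stats::rnorm(S)
    zu <- .unit(zraw)
    Traw <- vapply(hosts, function(h)
      moduleSign[h] * sqrt(rho) * zraw + sqrt(1 - rho) * stats::rnorm(S),
      numeric(S))
    Tunit <- apply(Traw, 2L, .unit)
    Reg <- Tunit
    Emit <- cfg@hostScale * Tunit
    Mprime <- matrix(0, S, cfg@nHosts, dimnames = list(NULL, hosts))
    for (h in hosts) {
      sc <- scenarios[[h]]
      if (sc == "independent_promoter") {
        Reg[, h] <- .unit(stats::rnorm(S))
      } else if (sc == "mirna_targeted_host") {
        m <- .unit(stats::rnorm(S))
        Mprime[, h] <- m
        deg <- Traw[, h] - cfg@decoupleImpact * m * sqrt(sum(Traw[, h]^2))
        Emit[, h] <- cfg@hostScale * .unit(deg)
      }
    }
    TGm <- vapply(targets, function(tg) {
      e <- rep(baseT, S) - stats::rnorm(1, 0, cfg@confounderSd) * zu
      for (i in which(edges$target == tg)) {
        h <- edges$host[i]
        e <- e - edges$w[i] * Reg[, h]
        if (scenarios[[h]] == "mirna_targeted_host")
          e <- e - cfg@sharedMirWeight * Mprime[, h]
      }
      e + stats::rnorm(S, 0, cfg@noiseSd)
    }, numeric(S))
    bgB <- stats::runif(cfg@nBackground, cfg@baselineRange[1L],
                        cfg@baselineRange[2L])
    bgS <- stats::runif(cfg@nBackground, cfg@bgSdRange[1L], cfg@bgSdRange[2L])
    BG <- matrix(stats::rnorm(cfg@nBackground * S), cfg@nBackground, S)
    BG <- BG * bgS + bgB
    E <- rbind(t(Emit), t(TGm), BG)
    rownames(E) <- c(hosts, targets,
                     sprintf("BG%04d", seq_len(cfg@nBackground)))
    colnames(E) <- sprintf("s%02d", seq_len(S))
    datasets[[k]] <- ExpressionDataset(E, sprintf("SIM%03d", k))
  }
  list(datasets = datasets, hostMap = hostMap, targetMap = targetMap,
       truth = new("GroundTruth", edges = edges, scenarios = scenarios))
}

#' Write a simulated compendium to disk in the reader formats
#'
#' @param sim result of \code{\link{simulateCompendium}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCompendium <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in sim$datasets) {
    m <- exprValues(ds)
    # full-precision formatting so files round-trip to identical doubles
    chr <- array(sprintf("%.17g", m), dim(m))
    df <- data.frame(gene_id = rownames(m), chr, check.names = FALSE)
    names(df) <- c("gene_id", colnames(m))
    utils::write.table(df, file.path(dir, paste0(datasetId(ds), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  hm <- sim$hostMap; names(hm) <- c("mirna_id", "host_gene_symbol")
  tm <- sim$targetMap; names(tm) <- c("mirna_id", "target_gene_symbol")
  utils::write.table(hm, file.path(dir, "host_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tm, file.path(dir, "target_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Evaluate recovery of planted regulation
#'
#' Compares the classified interactions with the ground truth: an edge is
#' recovered when its pair is significant and negative. Sensitivity is over
#' all planted (host, target) pairs (a planted pair never scored counts as
#' missed); specificity and precision are over scored non-planted pairs.
#' If a surrogacy report is supplied, per-scenario call accuracy is added:
#' a coupled host should be a good surrogate, a decoupled host (independent
#' promoter or miRNA-targeted) should be called bad or uninformative.
#'
#' @param scores annotated data.frame from \code{\link{classifyInteractions}}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param report optional data.frame from \code{\link{classifyHosts}}.
#' @return List: sensitivity, specificity, precision, nPlanted, nScored;
#'   plus surrogacyAccuracy and scenarioAccuracy when \code{report} given.
#' @export
evaluateRecovery <- function(scores, truth, report = NULL) {
  stopifnot(is(truth, "GroundTruth"),
            all(c("significant", "negative") %in% names(scores)))
  planted <- paste(truth@edges$host, truth@edges$target)
  if (!all(unique(truth@edges$host) %in%
           c(scores$host, names(truth@scenarios))))
    stop("ground truth references hosts unknown to the score table")
  key <- paste(scores$host, scores$target)
  isPlanted <- key %in% planted
  recovered <- scores$negative
  sens <- if (length(planted)) sum(recovered[isPlanted]) / length(planted)
          else NA_real_
  spec <- if (any(!isPlanted)) 1 - mean(recovered[!isPlanted]) else NA_real_
  prec <- if (sum(recovered)) mean(isPlanted[recovered]) else NA_real_
  out <- list(sensitivity = sens, specificity = spec, precision = prec,
              nPlanted = length(planted), nScored = nrow(scores))
  if (!is.null(report)) {
    sc <- truth@scenarios[report$host]
    ok <- ifelse(sc == "coupled", report$call == "good_surrogate",
                 report$call %in% c("bad_surrogate", "uninformative"))
    out$surrogacyAccuracy <- mean(ok)
    out$scenarioAccuracy <- vapply(split(ok, sc), mean, 0)
  }
  out
}
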