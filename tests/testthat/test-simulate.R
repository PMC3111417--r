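smallCfg <- function(...) {
  args <- list(nDatasets = 3, nSamples = 12, nHosts = 6, nTargets = 4,
               nBackground = 80, edgesPerTarget = 2, nDecoys = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulationConfig, args)
}

test_that("a seeded config reproduces the compendium exactly", {
  a <- simulateCompendium(smallCfg(seed = 9))
  b <- simulateCompendium(smallCfg(seed = 9))
  expect_identical(lapply(a$datasets, exprValues),
                   lapply(b$datasets, exprValues))
  expect_identical(a$targetMap, b$targetMap)
  expect_identical(plantedEdges(a$truth), plantedEdges(b$truth))
  d <- simulateCompendium(smallCfg(seed = 10))
  expect_false(identical(exprValues(a$datasets[[1]]),
                         exprValues(d$datasets[[1]])))
})

test_that("the generator emits consistent annotation and truth", {
  sim <- simulateCompendium(smallCfg(seed = 4, mirnasPerHost = 2))
  expect_equal(nrow(sim$hostMap), 12L)   # 6 hosts x 2 miRNAs
  edges <- plantedEdges(sim$truth)
  expect_equal(nrow(edges), 8L)          # 4 targets x 2 regulators
  # every planted pair appears in the putative map through each host miRNA
  key <- unique(paste(sim$hostMap$host[match(sim$targetMap$mirna,
                                             sim$hostMap$mirna)],
                      sim$targetMap$target))
  expect_true(all(paste(edges$host, edges$target) %in% key))
  # decoys extend the putative map beyond the truth
  expect_gt(length(key), nrow(edges))
  # a config with no planted edges yields pure-noise targets
  sim0 <- simulateCompendium(smallCfg(seed = 4, edgesPerTarget = 0,
                                      nDecoys = 3))
  expect_equal(nrow(plantedEdges(sim0$truth)), 0L)
  expect_equal(length(unique(sim0$targetMap$target)), 4L)
})

test_that("infeasible configs are rejected", {
  expect_error(smallCfg(edgesPerTarget = 5, nDecoys = 3),
               "more regulators")
  expect_error(smallCfg(scenarios = rep("coupled", 2)), "one entry per host")
  expect_error(smallCfg(noiseSd = -1), "noiseSd")
  expect_error(smallCfg(edges = data.frame(host = "HOST99", target = "TG01",
                                           w = 1)), "unknown host")
})

test_that("a noiseless coupled edge is recovered exactly", {
  cfg <- simulationConfig(nDatasets = 1, nSamples = 10, nHosts = 2,
                          nTargets = 1, nBackground = 600, nDecoys = 0,
                          edgesPerTarget = 1,
                          noiseSd = 0, confounderSd = 0, seed = 6,
                          edges = data.frame(host = "HOST01", target = "TG01",
                                             w = 1))
  sim <- simulateCompendium(cfg)
  ds <- filterGenes(sim$datasets[[1]])
  x <- normalizeHostProfile(ds, "HOST01")
  d <- computeDownregulation(ds, "TG01")
  fit <- fitULM(matrix(x, dimnames = list(NULL, "HOST01")), d)
  expect_equal(unname(fit$rescaled), 1)
  # the raw weight is the planted one up to the small column-mean residue
  expect_equal(unname(fit$raw), 1, tolerance = 0.1)
})

test_that("emitted datasets satisfy the model's preprocessing invariants", {
  sim <- simulateCompendium(smallCfg(seed = 12))
  ds <- filterGenes(sim$datasets[[1]])
  m <- exprValues(ds)
  # mean-centering of the down-regulation vectors over the gene universe
  dAll <- vapply(rownames(m), function(g) computeDownregulation(ds, g),
                 numeric(ncol(m)))
  expect_lt(max(abs(rowSums(dAll))), 1e-9)
  # hosts survive the low-signal filter and normalize to unit length
  for (h in unique(sim$hostMap$host)) {
    x <- normalizeHostProfile(ds, h)
    expect_equal(sum(x^2), 1, tolerance = 1e-9)
  }
})

test_that("per-dataset weights are unbiased for the planted effect", {
  # coupled scenario at signal-to-noise >= 1 over 50 datasets: the mean raw
  # weight across datasets stays within 3 standard errors of w* = 1
  cfg <- simulationConfig(nDatasets = 50, nSamples = 20, nHosts = 4,
                          nTargets = 3, nBackground = 2000,
                          edgesPerTarget = 2, nDecoys = 1, noiseSd = 0.5,
                          confounderSd = 1, seed = 13)
  sim <- simulateCompendium(cfg)
  datasets <- lapply(sim$datasets, filterGenes)
  designs <- buildDesigns(sim$hostMap, sim$targetMap)
  wt <- fitWeightTable(datasets, designs, "ULM")
  edges <- plantedEdges(sim$truth)
  for (i in seq_len(nrow(edges))) {
    w <- wt$raw[wt$host == edges$host[i] & wt$target == edges$target[i]]
    expect_gte(length(w), 45)
    se <- sd(w) / sqrt(length(w))
    expect_lt(abs(mean(w) - edges$w[i]), 3 * se + 0.05)
  }
})

test_that("recovery metrics match hand-computed values", {
  truth <- new("GroundTruth",
               edges = data.frame(host = c("H1", "H2"),
                                  target = c("T1", "T2"), w = 1),
               scenarios = c(H1 = "coupled", H2 = "coupled"))
  sc <- data.frame(method = "ULM", host = c("H1", "H2", "H1"),
                   target = c("T1", "T2", "T2"), n_datasets = 5,
                   p_real = c(1e-4, 1e-4, 0.4), p_perm = 0.5,
                   mean_weight = c(0.3, 0.3, 0), null_mean = 0,
                   sign = c("negative", "negative", "negative"),
                   stringsAsFactors = FALSE)
  ann <- classifyInteractions(sc, 0.01)
  m <- evaluateRecovery(ann, truth)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$precision, 1)
  # nothing predicted: zero sensitivity
  m0 <- evaluateRecovery(classifyInteractions(sc, 1e-9), truth)
  expect_equal(m0$sensitivity, 0)
  # surrogacy accuracy from a report
  rep1 <- classifyHosts(ann, 0.01)
  m2 <- evaluateRecovery(ann, truth, rep1)
  expect_equal(m2$surrogacyAccuracy, 1)
})

test_that("written compendia round-trip through the readers", {
  sim <- simulateCompendium(smallCfg(seed = 21))
  dir <- withr::local_tempdir()
  writeCompendium(sim, dir)
  ds <- readExpressionTSV(file.path(dir, "SIM001.tsv"))
  expect_equal(exprValues(ds), exprValues(sim$datasets[[1]]),
               tolerance = 1e-12)
  hm <- readHostMap(file.path(dir, "host_map.tsv"))
  tm <- readTargetMap(file.path(dir, "target_map.tsv"))
  expect_identical(hm$host, sim$hostMap$host)
  expect_identical(nrow(tm), nrow(sim$targetMap))
})
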