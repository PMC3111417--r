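test_that("host permutation is fixed-point-free, distinct and seeded", {
  # two-host universe: the swap is forced
  expect_identical(permuteHosts(c("A", "B"), c("A", "B")), c("B", "A"))
  expect_identical(permuteHosts("A", c("A", "B")), "B")
  expect_error(permuteHosts("A", "A"), "permutation impossible")
  expect_error(permuteHosts(c("A", "B", "C"), c("A", "B")), "more columns")
  # full identity never occurs; draws are valid relabellings
  uni <- sprintf("H%d", 1:5)
  set.seed(8)
  for (i in 1:200) {
    p <- permuteHosts(uni, uni)
    expect_true(all(p != uni))
    expect_identical(sort(p), uni)
  }
  # design scope permutes within the design's own columns
  set.seed(9)
  p <- permuteHosts(c("A", "B", "C"), sprintf("H%d", 1:9), scope = "design")
  expect_identical(sort(p), c("A", "B", "C"))
  # same seed, same draw
  set.seed(123); a <- permuteHosts(uni, uni)
  set.seed(123); b <- permuteHosts(uni, uni)
  expect_identical(a, b)
})

test_that("null pool counts coefficients and excludes degenerate fits", {
  set.seed(42)
  genes <- c("H1", "H2", "H3", "H4", "TG", sprintf("B%d", 1:30))
  m <- matrix(rnorm(length(genes) * 12, 10), length(genes), 12,
              dimnames = list(genes, sprintf("s%d", 1:12)))
  ds <- ExpressionDataset(m, "one")
  hm <- data.frame(mirna = paste0("m", 1:4), host = paste0("H", 1:4))
  tm <- data.frame(mirna = c("m1", "m2", "m3"), target = "TG")
  designs <- buildDesigns(hm, tm)
  pool <- buildNullPool(list(ds), designs, "ULM", nPerms = 1, seed = 1)
  # one target, one dataset, three columns, one permutation
  expect_length(nullWeights(pool), 3L)
  expect_identical(pool@permWeights$host, c("H1", "H2", "H3"))
  pool2 <- buildNullPool(list(ds), designs, "ULM", nPerms = 5, seed = 1)
  expect_length(nullWeights(pool2), 15L)
  # a zero down-regulation vector makes every permuted fit degenerate and
  # the pool empty: set the target equal to the mean of the other genes,
  # which is then also the mean of all genes
  m0 <- m
  m0["TG", ] <- colMeans(m[setdiff(genes, "TG"), ])
  ds0 <- ExpressionDataset(m0, "deg")
  expect_error(buildNullPool(list(ds0), designs, "ULM", seed = 1),
               "empty null pool")
})

test_that("rank-sum P-values are exact, symmetric and tie-safe", {
  # the extreme split: U = 0 occurs in 1 of choose(6,3) = 20 assignments
  expect_equal(wmwTwoSided(1:3, 4:6), 0.1)
  expect_equal(wmwTwoSided(4:6, 1:3), 0.1)  # two-sided symmetry
  # sample drawn from the pool's own values: no separation
  expect_equal(wmwTwoSided(c(1, 2), c(1, 2)), 1)
  set.seed(3)
  x <- rnorm(5); y <- rnorm(40)
  expect_equal(wmwTwoSided(x, y), wmwTwoSided(y, x), tolerance = 1e-12)
  expect_error(wmwTwoSided(numeric(), 1:3), ">= 1")
  # exact branch agrees with wilcox.test's exact P
  for (i in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:8, 1)
    x <- rnorm(n); y <- rnorm(m)
    expect_equal(wmwTwoSided(x, y), wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # tied / large-sample branch agrees with the corrected normal approximation
  for (i in 1:10) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(1:6, 30, replace = TRUE)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(wmwTwoSided(x, y), ref, tolerance = 1e-12)
  }
})

test_that("pair scoring separates shifted samples and keeps P uniform under null", {
  set.seed(14)
  pool <- rnorm(500)
  up <- scorePair(rnorm(30, mean = 3), rnorm(30), pool)
  expect_lt(up$p_real, 1e-6)
  expect_identical(up$sign, "negative")
  down <- scorePair(rnorm(30, mean = -3), rnorm(30), pool)
  expect_identical(down$sign, "non-negative")
  # real weights drawn from the null itself: P approximately uniform
  ps <- replicate(300, scorePair(rnorm(25), rnorm(25), pool)$p_real)
  expect_gt(suppressWarnings(ks.test(ps, punif))$p.value, 0.01)
})

test_that("the pooled null is symmetric about zero on no-signal data", {
  # large background universe so the small-universe column-mean artifact is
  # negligible relative to the pool's standard error
  cfg <- simulationConfig(nDatasets = 50, nSamples = 20, nHosts = 8,
                          nTargets = 10, nBackground = 4000,
                          edgesPerTarget = 0, nDecoys = 4, seed = 5)
  sim <- simulateCompendium(cfg)
  datasets <- lapply(sim$datasets, filterGenes)
  designs <- buildDesigns(sim$hostMap, sim$targetMap)
  pool <- buildNullPool(datasets, designs, "ULM", seed = 50)
  w <- nullWeights(pool)
  expect_lt(abs(mean(w)), 3 * sd(w) / sqrt(length(w)))
})

test_that("P and Q are reproducible bit for bit under a fixed seed", {
  cfg <- simulationConfig(nDatasets = 4, nSamples = 12, nHosts = 6,
                          nTargets = 4, nBackground = 100,
                          edgesPerTarget = 2, nDecoys = 1, seed = 2)
  sim <- simulateCompendium(cfg)
  datasets <- lapply(sim$datasets, filterGenes)
  designs <- buildDesigns(sim$hostMap, sim$targetMap)
  wt <- fitWeightTable(datasets, designs, "ULM")
  s1 <- scoreInteractions(wt, buildNullPool(datasets, designs, "ULM",
                                            seed = 77))
  s2 <- scoreInteractions(wt, buildNullPool(datasets, designs, "ULM",
                                            seed = 77))
  expect_identical(s1, s2)
  s3 <- scoreInteractions(wt, buildNullPool(datasets, designs, "ULM",
                                            seed = 78))
  expect_false(identical(s1$p_real, s3$p_real))
  # method mismatch is refused
  expect_error(scoreInteractions(wt, buildNullPool(datasets, designs, "CORR",
                                                   seed = 77)),
               "does not match")
})
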