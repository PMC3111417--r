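test_that("TSV reader round-trips a small matrix and preserves order", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsB\tsA", "Zgene\t1.5\t2", "Agene\t3\t4",
               "Mgene\t5\t-6"), tf)
  ds <- readExpressionTSV(tf, "t1")
  expect_s4_class(ds, "ExpressionDataset")
  expect_identical(geneIds(ds), c("Zgene", "Agene", "Mgene"))
  expect_identical(sampleIds(ds), c("sB", "sA"))
  expect_identical(datasetId(ds), "t1")
  expect_equal(exprValues(ds)["Mgene", "sA"], -6)
})

test_that("TSV reader rejects malformed input with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "A\t1\t2", "A\t3\t4"), tf)
  expect_error(readExpressionTSV(tf), "duplicate gene symbol.*A")
  writeLines(c("gene_id\ts1\ts2", "A\t1\tx2"), tf)
  expect_error(readExpressionTSV(tf), "non-numeric value 'x2'.*A.*s2")
  writeLines(c("gene_id\ts1\ts2", "A\t1"), tf)
  expect_error(readExpressionTSV(tf), "expected 3")
  writeLines("gene_id", tf)
  expect_error(readExpressionTSV(tf), "malformed")
})

test_that("missing values are carried through and dropped by filterGenes", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "A\tNA\t200", "B\t3\t4", "C\t\t5",
               "D\t30\t40"), tf)
  ds <- readExpressionTSV(tf)
  expect_true(anyNA(exprValues(ds)))
  kept <- filterGenes(ds, percentile = 0)
  # A has huge values but a missing cell: removed regardless of magnitude
  expect_identical(geneIds(kept), c("B", "D"))
})

test_that("low-signal filter drops genes below the percentile of max-abs", {
  # 10 genes whose per-gene max abs values are exactly 1..10; at the 10th
  # percentile (linear interpolation: 1.9) only the max=1 gene is below
  m <- t(vapply(1:10, function(i) c(i, -i / 2, i / 3), numeric(3)))
  dimnames(m) <- list(sprintf("g%02d", 1:10), c("s1", "s2", "s3"))
  ds <- ExpressionDataset(m, "pct")
  kept <- filterGenes(ds, 0.10)
  expect_identical(geneIds(kept), sprintf("g%02d", 2:10))
  # percentile 0 is a no-op on complete data
  expect_identical(exprValues(filterGenes(ds, 0)), exprValues(ds))
  # ties at the threshold are kept (strict less-than): per-gene maxima
  # (5, 5, 5, 9) put the median exactly at 5, and no gene is below it
  m2 <- cbind(s1 = c(5, 5, 5, 9), s2 = 1:4)
  rownames(m2) <- letters[1:4]
  expect_identical(geneIds(filterGenes(ExpressionDataset(m2, "t"), 0.5)),
                   letters[1:4])
})

test_that("raising the filter percentile never increases survivors", {
  ds <- tinyDataset(40, 6, seed = 42)
  counts <- vapply(seq(0, 0.9, by = 0.1),
                   function(p) nrow(filterGenes(ds, p)), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_error(filterGenes(ds, 1.000001), "percentile")
})

test_that("down-regulation is the per-sample mean minus the gene", {
  m <- matrix(c(1, 3, 3, 5), 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ds <- ExpressionDataset(m, "d")
  expect_equal(computeDownregulation(ds, "g1"), c(s1 = 1, s2 = 1))
  expect_equal(computeDownregulation(ds, "g2"), c(s1 = -1, s2 = -1))
  expect_error(computeDownregulation(ds, "nope"), "not present")
  # a gene equal to the column means has zero down-regulation:
  # gmid = (g1 + g2) / 2 is also the mean of all three rows
  ds3 <- ExpressionDataset(rbind(m, gmid = colMeans(m)), "d3")
  expect_equal(computeDownregulation(ds3, "gmid"), c(s1 = 0, s2 = 0))
})

test_that("down-regulation sums to zero over the gene universe", {
  set.seed(7)
  ds <- tinyDataset(20, 8)
  d <- vapply(geneIds(ds), function(g) computeDownregulation(ds, g),
              numeric(8))
  expect_lt(max(abs(rowSums(d))), 1e-9)
})

test_that("host profiles are unit-norm, scale-invariant and guarded", {
  m <- matrix(c(3, 4, 0, 0, 6, 8), 3, 2, byrow = TRUE,
              dimnames = list(c("h1", "zero", "h2"), c("s1", "s2")))
  ds <- ExpressionDataset(m, "h")
  expect_equal(normalizeHostProfile(ds, "h1"), c(s1 = 0.6, s2 = 0.8))
  # scale invariance: h2 = 2 * h1
  expect_equal(normalizeHostProfile(ds, "h2"),
               normalizeHostProfile(ds, "h1"))
  # idempotence on an already unit-norm row
  u <- exprValues(ds)["h1", ] / 5
  ds2 <- ExpressionDataset(rbind(u = u), "u")
  expect_equal(normalizeHostProfile(ds2, "u"), u)
  expect_error(normalizeHostProfile(ds, "zero"), "degenerate")
  expect_error(normalizeHostProfile(ds, "gone"),
               class = "intromiR_missing_host")
})

test_that("SOFT reader maps probes to symbols and collapses duplicates", {
  tf <- withr::local_tempfile(fileext = ".soft")
  writeLines(c(
    "^DATASET = GDS0001", "!dataset_title = toy",
    "!dataset_table_begin",
    "ID_REF\tIDENTIFIER\tGSM1\tGSM2",
    "p1\tGENEA\t1\t2",
    "p2\tGENEA\t3\t6",
    "p3\tGENEB\t5\t7",
    "p4\t--Control\t9\t9",
    "!dataset_table_end"), tf)
  ds <- readGeoSoft(tf, "gds")
  expect_setequal(geneIds(ds), c("GENEA", "GENEB"))
  expect_equal(exprValues(ds)["GENEA", ], c(GSM1 = 2, GSM2 = 4))  # mean
  dsf <- readGeoSoft(tf, "gds", collapse = "first")
  expect_equal(exprValues(dsf)["GENEA", ], c(GSM1 = 1, GSM2 = 2))
  dsm <- readGeoSoft(tf, "gds", collapse = "max")
  expect_equal(exprValues(dsm)["GENEA", ], c(GSM1 = 3, GSM2 = 6))
  # user-supplied probe map: unmapped probes dropped
  pm <- data.frame(probe = c("p1", "p3"), symbol = c("X", "Y"))
  dsp <- readGeoSoft(tf, "gds", probeMap = pm)
  expect_setequal(geneIds(dsp), c("X", "Y"))
})

test_that("ExpressionDataset validity rejects bad containers", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(ExpressionDataset(matrix(c(1, Inf, 2, 3), 2,
    dimnames = list(c("a", "b"), c("s1", "s2"))), "x"), "finite")
  expect_error(ExpressionDataset(matrix(1:4, 2), "x"), "symbols|labels")
})
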