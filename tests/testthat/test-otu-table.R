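test_that("count tables round-trip through TSV", {
  m <- matrix(c(1L, 2L, 3L, 4L), 2,
              dimnames = list(c("OTU_a", "OTU_b"), c("s1", "s2")))
  x <- OtuExperiment(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(x, path)
  y <- readCountTable(path)
  expect_identical(otuCounts(y)[rownames(m), colnames(m)], m)

  sim <- simulateCommunity(simulationConfig(nTrials = 1L, nOtus = 25L,
    nSensitive = 0L, effectSizes = numeric(0), seed = 2L))
  writeCountTable(sim$experiment, path)
  expect_identical(otuCounts(readCountTable(path)),
                   otuCounts(sim$experiment))
})

test_that("malformed count tables are rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#SampleID\tA\tB", "s1\t1\t2", "s2\t3"), path)
  expect_error(readCountTable(path), "line 3")
  writeLines(c("#SampleID\tA\tB", "s1\t1\t-2"), path)
  expect_error(readCountTable(path), "negative|non-integer")
  writeLines(c("#SampleID\tA\tB", "s1\t1\t2.5"), path)
  expect_error(readCountTable(path), "non-integer")
  writeLines(c("#SampleID\tA\tA", "s1\t1\t2"), path)
  expect_error(readCountTable(path), "duplicate OTU")
  writeLines(c("#SampleID\tA\tB", "s1\t1\t2", "s1\t1\t2"), path)
  expect_error(readCountTable(path), "duplicate sample")
})

test_that("metadata and taxonomy round-trip through TSV", {
  sim <- simulateStudy(simulationConfig(nTrials = 1L, nOtus = 15L,
    nSensitive = 1L, effectSizes = 4, seed = 3L))
  mdPath <- withr::local_tempfile(fileext = ".tsv")
  writeSampleMetadata(SummarizedExperiment::colData(sim$experiment), mdPath)
  md <- readSampleMetadata(mdPath)
  expect_setequal(rownames(md), sampleIds(sim$experiment))
  expect_setequal(unique(md$group), c("control", "treatment"))

  taxPath <- withr::local_tempfile(fileext = ".tsv")
  writeTaxonomy(taxonomyTable(sim$experiment), taxPath)
  tax <- readTaxonomy(taxPath)
  expect_setequal(rownames(tax), otuIds(sim$experiment))
  expect_identical(as.character(tax[otuIds(sim$experiment), "phylum"]),
                   as.character(taxonomyTable(sim$experiment)$phylum))
})

test_that("rarefaction hits the exact depth and drops shallow samples", {
  m <- matrix(c(10L, 0L, 0L,   3L, 3L, 0L,   2L, 1L, 0L), 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  expect_message(r <- rarefy(m, depth = 5, seed = 1L), "s3")
  expect_equal(colnames(r), c("s1", "s2"))
  expect_equal(unname(r[, "s1"]), c(5L, 0L, 0L))
  expect_true(all(colSums(r) == 5L))
  expect_true(all(r <= m[, colnames(r)]))
  expect_equal(attr(r, "dropped"), "s3")

  # depth equal to the total keeps the sample unchanged
  m2 <- matrix(c(3L, 3L), 2, dimnames = list(c("A", "B"), "s1"))
  expect_equal(unname(rarefy(m2, depth = 6)[, 1]), c(3L, 3L))
  expect_error(rarefy(m2, depth = 0), "depth")
})

test_that("rarefied counts follow the hypergeometric expectation", {
  m <- matrix(c(100L, 100L), 2, dimnames = list(c("A", "B"), "s1"))
  draws <- vapply(1:400, function(s) rarefy(m, depth = 50, seed = s)[1, 1],
                  numeric(1))
  # mean 25, sd of the mean ~ sqrt(50*.25*150/199)/20 ~ 0.153
  expect_lt(abs(mean(draws) - 25), 0.7)
})

test_that("rarefy on an OtuExperiment subsets metadata consistently", {
  sim <- simulateCommunity(simulationConfig(nTrials = 1L, nOtus = 20L,
    nSensitive = 0L, effectSizes = numeric(0),
    librarySizeRange = c(1000L, 2000L), seed = 4L))
  r <- rarefy(sim$experiment, depth = 1000, seed = 1L)
  expect_true(all(colSums(otuCounts(r)) == 1000L))
  expect_identical(sampleIds(r),
                   rownames(SummarizedExperiment::colData(r)))
})

test_that("relative abundances are proper compositions", {
  expect_equal(unname(relativeAbundance(
    matrix(c(2L, 2L), 2, dimnames = list(c("A", "B"), "s1")))[, 1]),
    c(0.5, 0.5))
  expect_equal(unname(relativeAbundance(
    matrix(c(1L, 0L, 3L), 3, dimnames = list(c("A", "B", "C"), "s1")))[, 1]),
    c(0.25, 0, 0.75))
  m <- randomCountMatrix(30, 8, seed = 5)
  rel <- relativeAbundance(m)
  expect_true(all(abs(colSums(rel) - 1) < 1e-12))
  expect_true(all(rel >= 0 & rel <= 1))
  m0 <- m; m0[, 2] <- 0L
  expect_error(relativeAbundance(m0), "s002")
})

test_that("rank aggregation sums counts and conserves totals", {
  m <- matrix(c(1L, 2L, 4L), 3,
              dimnames = list(c("o1", "o2", "o3"), "s1"))
  tax <- data.frame(row.names = c("o1", "o2", "o3"),
                    phylum = c("A", "A", "B"))
  agg <- aggregateByRank(m, tax, rank = "phylum")
  expect_equal(agg["A", "s1"], 3L)
  expect_equal(agg["B", "s1"], 4L)

  tax1 <- data.frame(row.names = rownames(m),
                     phylum = rep("OnlyOne", nrow(m)))
  agg1 <- aggregateByRank(m, tax1)
  expect_equal(dim(agg1), c(1L, 1L))
  expect_equal(unname(agg1[1, ]), unname(colSums(m)))

  expect_error(aggregateByRank(m, tax[1:2, , drop = FALSE]), "o3")
  routed <- aggregateByRank(m, tax[1:2, , drop = FALSE],
                            unclassified = TRUE)
  expect_equal(routed["unclassified", "s1"], 4L)
})

test_that("pooling prefixes trials, unions OTUs and conserves counts", {
  m1 <- matrix(5L, 1, 1, dimnames = list("o1", "s1"))
  m2 <- matrix(7L, 1, 1, dimnames = list("o2", "s1"))
  x1 <- makeExperiment(m1, group = "control", trial = "T1")
  x2 <- makeExperiment(m2, group = "control", trial = "T2")
  pooled <- poolExperiments(list(x1, x2))
  expect_equal(dim(pooled), c(2L, 2L))
  expect_equal(otuCounts(pooled)["o1", "T1.s1"], 5L)
  expect_equal(otuCounts(pooled)["o2", "T1.s1"], 0L)
  expect_equal(sum(otuCounts(pooled)), 12L)

  # same trial label twice -> id collision
  expect_error(poolExperiments(list(x1, x1)), "collision")

  sims <- lapply(1:4, function(t) simulateCommunity(simulationConfig(
    nTrials = 1L, nOtus = 30L, nSensitive = 0L,
    effectSizes = numeric(0), seed = 50L + t))$experiment)
  big <- poolExperiments(sims, trials = sprintf("T%d", 1:4))
  expect_equal(ncol(big), 96L)
  expect_equal(sum(otuCounts(big)), sum(vapply(sims, function(s)
    sum(otuCounts(s)), numeric(1))))
})

test_that("day filtering keeps matching samples and is idempotent", {
  m <- randomCountMatrix(10, 6, seed = 6)
  x <- OtuExperiment(m, sampleData = data.frame(
    row.names = colnames(m), trial = "T1",
    day = c(7L, 21L, 35L, 35L, 7L, 35L),
    group = rep(c("control", "treatment"), 3)))
  d35 <- filterToDay(x, 35)
  expect_equal(ncol(d35), 3L)
  expect_identical(otuCounts(filterToDay(d35, 35)), otuCounts(d35))
  expect_warning(d99 <- filterToDay(x, 99), "no samples")
  expect_equal(ncol(d99), 0L)
})
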