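test_that("shadow features are per-column permutations, independent and reproducible", {
  set.seed(1)
  X <- cbind(f1 = rnorm(20), f2 = rep(3, 20), f3 = 1:20)
  aug <- makeShadowFeatures(X, seed = 4L)
  expect_equal(colnames(aug),
               c("f1", "f2", "f3", "shadow__f1", "shadow__f2", "shadow__f3"))
  for (f in c("f1", "f2", "f3"))
    expect_equal(sort(aug[, paste0("shadow__", f)]), sort(X[, f]))
  expect_equal(aug[, "shadow__f2"], X[, "f2"])  # constants stay constant
  expect_identical(makeShadowFeatures(X, seed = 4L), aug)
  expect_false(identical(makeShadowFeatures(X, seed = 5L), aug))
  expect_error(makeShadowFeatures(X[1, , drop = FALSE]), ">= 2 samples")
})

test_that("shadow-label correlations are centred at zero", {
  set.seed(2)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  feat <- y + rnorm(n, 0, 0.5)          # genuinely informative feature
  X <- cbind(f = feat)
  shadowCors <- vapply(1:200, function(s)
    cor(makeShadowFeatures(X, seed = s)[, "shadow__f"], y), numeric(1))
  expect_gt(cor(feat, y), 0.5)
  expect_lt(abs(mean(shadowCors)), 3 * sd(shadowCors) / sqrt(200))
})

test_that("a feature equal to the label dominates forest importance", {
  set.seed(3)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- cbind(signal = as.numeric(y),
             matrix(rnorm(n * 9), n,
                    dimnames = list(NULL, sprintf("noise%d", 1:9))))
  vim <- fitForestVim(makeShadowFeatures(X, seed = 1L), y,
                      nTrees = 200, seed = 1L)
  expect_equal(names(which.max(vim)), "signal")
  expect_identical(vim, fitForestVim(makeShadowFeatures(X, seed = 1L), y,
                                     nTrees = 200, seed = 1L))
  expect_error(fitForestVim(makeShadowFeatures(X, seed = 1L),
                            rep("a", n)), "both classes")
})

test_that("real and shadow importances are exchangeable under the null", {
  # label independent of X: KS cannot tell the two distributions apart
  realV <- c(); shadV <- c()
  for (s in 1:100) {
    set.seed(s)
    n <- 20
    X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, sprintf("f%d", 1:5)))
    y <- factor(rep(c("a", "b"), each = n / 2))
    vim <- fitForestVim(makeShadowFeatures(X, seed = s), y,
                        nTrees = 60, seed = 1000 + s)
    shad <- grepl("^shadow__", names(vim))
    realV <- c(realV, vim[!shad]); shadV <- c(shadV, vim[shad])
  }
  expect_gt(suppressWarnings(ks.test(realV, shadV)$p.value), 0.01)
})

test_that("stability matrices have the declared shape and are reproducible", {
  set.seed(4)
  X <- matrix(rnorm(40), 10, dimnames = list(NULL, sprintf("f%d", 1:4)))
  y <- factor(rep(c("a", "b"), each = 5))
  cfg <- erfConfig(nRepetitions = 2L, nTrees = 50L, seed = 6L)
  v <- stabilityVims(X, y, cfg)
  expect_equal(dim(v), c(8L, 2L))
  expect_equal(rownames(v)[5:8], paste0("shadow__", colnames(X)))
  expect_identical(v, stabilityVims(X, y, cfg))
  expect_error(erfConfig(nRepetitions = 1L), "nRepetitions")
})

test_that("a strong planted feature has stable importance across refits", {
  sim <- simulateCommunity(simulationConfig(nTrials = 1L, nPerGroup = 24L,
    nOtus = 30L, nSensitive = 1L, effectSizes = 8, seed = 7L))
  g <- factor(SummarizedExperiment::colData(sim$experiment)$group)
  X <- t(relativeAbundance(sim$experiment))
  v <- stabilityVims(X, g, erfConfig(nRepetitions = 10L, nTrees = 200L,
                                     seed = 8L))
  planted <- v["OTU_0001", ]
  expect_lt(sd(planted) / mean(planted), 1)   # CV << 1 at this effect size
})

test_that("welch p-values match the independent t-test oracle", {
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(sample(2:20, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(2:20, 1), mean = runif(1, -1, 1))
    expect_equal(welchOneSidedP(x, y),
                 t.test(x, y, alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
  # degenerate conventions
  expect_equal(welchOneSidedP(c(1, 1), c(0, 0)), 0)
  expect_equal(welchOneSidedP(c(0, 0), c(1, 1)), 1)
  expect_equal(welchOneSidedP(c(1, 1), c(1, 1)), 0.5)
})

test_that("relevance likelihoods separate signal from the shadow envelope", {
  v <- rbind(good = c(0.9, 0.9, 0.9, 0.9),
             shadow__a = c(0, 0, 0, 0.01),
             shadow__b = c(0.001, 0, 0.002, 0))
  res <- relevanceLikelihood(v)
  expect_lt(res["good", "p_value"], 1e-6)
  expect_gt(res["good", "likelihood_pct"], 99.999)

  # a feature identical to the envelope is indistinguishable from it
  ref <- apply(v[2:3, ], 2, max)
  v2 <- rbind(tied = ref, v[2:3, ])
  expect_equal(relevanceLikelihood(v2)["tied", "p_value"], 0.5)
  expect_error(relevanceLikelihood(v[1, , drop = FALSE] ), "no shadow")
})

test_that("selection gates and ordering behave as documented", {
  v <- rbind(a = c(0.5, 0.6), b = c(0.0004, 0.0002), c = c(0.5, 0.61),
             shadow__a = c(0.001, 0.002), shadow__b = c(0, 0),
             shadow__c = c(0.001, 0.0015))
  res <- relevanceLikelihood(v)
  all_in <- selectRelevant(res, erfConfig(likelihoodThreshold = 0,
                                          importanceThreshold = 0))
  expect_true(all(all_in$selected))
  # sorted by mean importance, descending
  expect_equal(all_in$otu_id,
               all_in$otu_id[order(-all_in$mean_vim, all_in$otu_id)])
  # importance gate removes the weak feature regardless of likelihood
  gated <- selectRelevant(res, erfConfig(likelihoodThreshold = 0,
                                         importanceThreshold = 0.001))
  expect_false(gated[gated$otu_id == "b", "selected"])
})

test_that("direction annotation reflects group means and handles ties", {
  # control mean 0.02, treatment mean 0.04 for OTU A (a rare OTU keeps the
  # zero-replacement pseudo-fraction negligible)
  m <- matrix(c(
    200L, 9799L, 1L,
    200L, 9800L, 0L,
    400L, 9600L, 0L,
    400L, 9599L, 1L), nrow = 3,
    dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:4)))
  x <- makeExperiment(m, group = c("control", "control",
                                   "treatment", "treatment"))
  d <- directionOfChange(x)
  expect_equal(d["A", "fold_change"], 2, tolerance = 1e-2)
  expect_equal(d["A", "direction"], "increased")
  expect_equal(d["B", "direction"], "decreased")
  expect_error(directionOfChange(x, otuIds = "missing"), "absent")

  # exactly tied means -> unchanged
  m2 <- matrix(c(5L, 5L, 5L, 5L, 3L, 7L, 7L, 3L), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), sprintf("s%d", 1:4)))
  x2 <- makeExperiment(m2, group = c("control", "treatment",
                                     "control", "treatment"))
  expect_equal(directionOfChange(x2)["A", "direction"], "unchanged")
})

test_that("planted directions are recovered at moderate effect sizes", {
  for (eff in c(2, 4)) {
    sim <- simulateCommunity(simulationConfig(nTrials = 2L,
      nOtus = 50L, nSensitive = 2L, effectSizes = c(eff, 1 / eff),
      seed = 60L + eff))
    d <- directionOfChange(sim$experiment,
                           otuIds = sim$groundTruth$otu_id)
    expect_equal(unname(d$direction), sim$groundTruth$direction)
  }
})

test_that("the selected set is invariant to feature order", {
  sim <- simulateCommunity(simulationConfig(nTrials = 1L, nPerGroup = 24L,
    nOtus = 40L, nSensitive = 2L, effectSizes = c(8, 0.125), seed = 70L))
  cfg <- erfConfig(nRepetitions = 10L, nTrees = 200L, seed = 71L)
  res1 <- erfRelevance(sim$experiment, cfg)
  shuffled <- sim$experiment[sample(nrow(sim$experiment)), ]
  res2 <- erfRelevance(shuffled, cfg)
  expect_setequal(selectedOtus(res1), selectedOtus(res2))
  expect_true(all(sim$groundTruth$otu_id %in% selectedOtus(res1)))
})

test_that("mean likelihood of a planted OTU grows with its effect size", {
  liks <- vapply(c(1.1, 1.5, 2.5), function(eff) {
    per_seed <- vapply(1:10, function(s) {
      sim <- simulateCommunity(simulationConfig(nTrials = 1L,
        nPerGroup = 10L, nOtus = 60L, nSensitive = 1L, effectSizes = eff,
        seed = 200L + s))
      res <- erfRelevance(sim$experiment,
                          erfConfig(nRepetitions = 6L, nTrees = 100L,
                                    seed = 300L + s))
      relevanceTable(res)["OTU_0001", "likelihood_pct"]
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  expect_true(all(diff(liks) >= 0))
})

test_that("erfRelevance output is internally consistent", {
  sim <- simulateCommunity(simulationConfig(nTrials = 1L, nOtus = 25L,
    nSensitive = 1L, effectSizes = 8, seed = 80L))
  res <- erfRelevance(sim$experiment,
                      erfConfig(nRepetitions = 5L, nTrees = 100L,
                                seed = 81L))
  rt <- relevanceTable(res)
  expect_setequal(rt$otu_id, otuIds(sim$experiment))
  expect_true(all(rt$likelihood_pct >= 0 & rt$likelihood_pct <= 100))
  expect_true(all(rt$selected ==
    (rt$likelihood_pct >= 99.5 & rt$mean_vim >= 0.001)))
  expect_true(all((rt$fold_change > 1) == (rt$direction == "increased")))
  expect_equal(dim(vimMatrix(res)), c(50L, 5L))
})
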