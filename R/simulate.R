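#' Simulate a multi-trial two-group microbiome count table
#'
#' Generates group-labelled OTU counts with known planted
#' treatment-sensitive OTUs so downstream selection can be validated against
#' ground truth. Baseline relative abundances are drawn once per OTU from a
#' log-normal (heavy-tailed, a few dominant phylotypes over a long tail of
#' rare taxa); each trial perturbs them by a small log-normal offset; the
#' treatment group's composition multiplies each sensitive OTU by its fold
#' change before renormalisation, so "increased" OTUs mechanically depress
#' the rest slightly (the compositional artefact real data carry). Each
#' sample then draws a library size uniformly from `librarySizeRange`,
#' applies a per-entry zero-inflation mask to its composition, and resamples
#' counts multinomially, so per-sample totals stay inside the configured
#' range.
#'
#' The planted sensitive OTUs are the first `nSensitive` ids
#' (`OTU_0001`, ...); their direction is `increased` when the effect size
#' exceeds 1.
#'
#' @param config A [SimulationConfig-class] from [simulationConfig()].
#' @return A list with `experiment` (an [OtuExperiment-class]; `colData`
#'   carries `trial`, `day` (35) and `group`) and `groundTruth` (a
#'   `DataFrame` of `otu_id`, `direction`, `effect_size` for the planted
#'   OTUs).
#' @export
#' @examples
#' sim <- simulateCommunity(simulationConfig(nTrials = 1L, nOtus = 20L,
#'   nSensitive = 1L, effectSizes = 8, seed = 7L))
#' sim$experiment
#' sim$groundTruth
simulateCommunity <- function(config = simulationConfig()) {
  validObject(config)
  p <- config@nOtus
  otuIds <- sprintf("OTU_%04d", seq_len(p))
  seeds <- deriveSeeds(config@seed, 2L + config@nTrials)

  base <- withSeed(seeds[1],
                   rlnorm(p, config@baseLogMean, config@baseLogSd))
  # Planted sensitive OTUs sit at fixed moderate-to-high quantiles of the
  # same baseline distribution: a "diet-sensitive taxon" is by construction
  # an observable one, so its ground-truth direction is identifiable at the
  # simulated sequencing depths (a taxon of expected depth << 1 read would
  # carry a planted effect no data could reveal).
  if (config@nSensitive > 0L)
    base[seq_len(config@nSensitive)] <- stats::qlnorm(
      seq(0.70, 0.98, length.out = config@nSensitive),
      config@baseLogMean, config@baseLogSd)
  offsets <- withSeed(seeds[2],
                      matrix(rnorm(config@nTrials * p, 0, config@trialSd),
                             nrow = config@nTrials))

  effect <- rep(1, p)
  if (config@nSensitive > 0L)
    effect[seq_len(config@nSensitive)] <- config@effectSizes

  counts <- NULL
  ids <- character(0)
  meta <- list()
  for (t in seq_len(config@nTrials)) {
    aTrial <- base * exp(offsets[t, ])
    comp <- list(control = aTrial / sum(aTrial),
                 treatment = {
                   x <- aTrial * effect
                   x / sum(x)
                 })
    trialCounts <- withSeed(seeds[2L + t], {
      out <- matrix(0L, nrow = p, ncol = 2L * config@nPerGroup)
      j <- 0L
      for (grp in c("control", "treatment")) {
        for (i in seq_len(config@nPerGroup)) {
          j <- j + 1L
          L <- sample(config@librarySizeRange[1]:config@librarySizeRange[2],
                      1L)
          pr <- comp[[grp]]
          if (config@zeroInflation > 0) {
            mask <- rbinom(p, 1L, config@zeroInflation) == 1L
            if (!all(mask)) pr <- pr * !mask
          }
          out[, j] <- rmultinom(1L, L, pr / sum(pr))[, 1]
        }
      }
      out
    })
    trialIds <- sprintf("T%d_%s_%02d", t,
                        rep(c("control", "treatment"),
                            each = config@nPerGroup),
                        rep(seq_len(config@nPerGroup), 2L))
    counts <- cbind(counts, trialCounts)
    ids <- c(ids, trialIds)
    meta[[t]] <- data.frame(
      sample_id = trialIds, trial = sprintf("T%d", t), day = 35L,
      group = rep(c("control", "treatment"), each = config@nPerGroup))
  }
  dimnames(counts) <- list(otuIds, ids)
  sampleData <- do.call(rbind, meta)
  truth <- S4Vectors::DataFrame(
    otu_id = otuIds[seq_len(config@nSensitive)],
    direction = ifelse(config@effectSizes > 1, "increased", "decreased"),
    effect_size = config@effectSizes)
  list(experiment = OtuExperiment(counts, sampleData = sampleData),
       groundTruth = truth)
}

#' Simulate a rooted binary phylogeny over OTUs
#'
#' Random binary topology with strictly positive uniform branch lengths;
#' a fixture for UniFrac, not an inference of real phylogeny.
#'
#' @param otuIds Character vector of at least 2 leaf labels.
#' @param seed RNG seed.
#' @return A rooted `ape::phylo` with one leaf per id.
#' @export
#' @examples
#' simulateTree(c("OTU_1", "OTU_2", "OTU_3"), seed = 1L)
simulateTree <- function(otuIds, seed = 1L) {
  if (length(otuIds) < 2L)
    badInput("otuIds must contain at least 2 ids")
  if (anyDuplicated(otuIds))
    badInput("otuIds must be unique")
  withSeed(seed, {
    tree <- ape::rtree(length(otuIds), rooted = TRUE)
    tree$edge.length <- runif(length(tree$edge.length), 0.05, 1)
    tree$tip.label <- as.character(otuIds)
    tree
  })
}

# Phylum weights loosely matching reported broiler-cecum composition:
# Firmicutes-dominant with Bacteroidetes and Proteobacteria next.
defaultPhylaWeights <- c(
  Firmicutes = 0.70, Bacteroidetes = 0.12, Proteobacteria = 0.09,
  Actinobacteria = 0.04, Cyanobacteria = 0.02, Tenericutes = 0.01,
  Euryarchaeota = 0.008, Deferribacteres = 0.005, Verrucomicrobia = 0.004,
  Lentisphaerae = 0.002, Thermotogae = 0.001)

#' Simulate a taxonomy table
#'
#' Assigns each OTU a phylum by weighted sampling and synthesises a nested
#' lineage (class, order, family, genus) beneath it; `nearest_species` is
#' filled for a minority of OTUs, mirroring partial reference coverage.
#'
#' @param otuIds Character vector of OTU ids.
#' @param phylaWeights Named nonnegative weights, not all zero.
#' @param seed RNG seed.
#' @param anchor Optional named character vector `otu_id -> phylum` forcing
#'   specific assignments (used to plant phylum-level structure over the
#'   sensitive OTUs).
#' @return `DataFrame` keyed by OTU id with columns `phylum`, `class`,
#'   `order`, `family`, `genus`, `nearest_species` (NA when unresolved).
#' @export
#' @examples
#' simulateTaxonomy(sprintf("OTU_%02d", 1:5), seed = 3L)
simulateTaxonomy <- function(otuIds, phylaWeights = defaultPhylaWeights,
                             seed = 1L, anchor = NULL) {
  if (length(otuIds) == 0L)
    badInput("otuIds must be non-empty")
  if (is.null(names(phylaWeights)) || any(phylaWeights < 0) ||
      sum(phylaWeights) <= 0)
    badInput("phylaWeights must be named, nonnegative, not all zero")
  withSeed(seed, {
    phyla <- sample(names(phylaWeights), length(otuIds), replace = TRUE,
                    prob = phylaWeights / sum(phylaWeights))
    names(phyla) <- otuIds
    if (!is.null(anchor)) {
      unknown <- setdiff(names(anchor), otuIds)
      if (length(unknown))
        badInput("anchor names absent from otuIds: %s",
                 paste(unknown, collapse = ", "))
      phyla[names(anchor)] <- anchor
    }
    lineage <- function(phy, level, k) sprintf("%s_%s%d", phy, level, k)
    tax <- S4Vectors::DataFrame(
      otu_id = otuIds,
      phylum = unname(phyla),
      class = lineage(phyla, "c", sample.int(2L, length(otuIds), TRUE)),
      order = lineage(phyla, "o", sample.int(4L, length(otuIds), TRUE)),
      family = lineage(phyla, "f", sample.int(8L, length(otuIds), TRUE)),
      genus = lineage(phyla, "g", sample.int(20L, length(otuIds), TRUE)),
      nearest_species = ifelse(
        runif(length(otuIds)) < 0.3,
        lineage(phyla, "sp", sample.int(40L, length(otuIds), TRUE)),
        NA_character_),
      row.names = otuIds)
    tax
  })
}

#' Simulate the full study scenario
#'
#' Convenience wrapper producing the complete fixture the pipeline consumes:
#' the multi-trial count table with planted sensitive OTUs, a taxonomy in
#' which planted increased OTUs are anchored to Bacteroidetes and planted
#' decreased OTUs to Firmicutes (the phylum-level shift the analysis is
#' meant to expose), and a random rooted phylogeny.
#'
#' @param config A [SimulationConfig-class].
#' @return List of `experiment` (with taxonomy attached), `tree`,
#'   `groundTruth`.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  sim <- simulateCommunity(config)
  # streams 1..(2 + nTrials) are consumed by simulateCommunity
  seeds <- deriveSeeds(config@seed, 4L + config@nTrials)
  taxSeed <- seeds[3L + config@nTrials]
  treeSeed <- seeds[4L + config@nTrials]
  truth <- sim$groundTruth
  anchor <- NULL
  if (nrow(truth) > 0)
    anchor <- setNames(
      ifelse(truth$direction == "increased", "Bacteroidetes", "Firmicutes"),
      truth$otu_id)
  tax <- simulateTaxonomy(otuIds(sim$experiment), seed = taxSeed,
                          anchor = anchor)
  rowData(sim$experiment) <- tax[otuIds(sim$experiment), ]
  tree <- simulateTree(otuIds(sim$experiment), seed = treeSeed)
  list(experiment = sim$experiment, tree = tree, groundTruth = truth)
}
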