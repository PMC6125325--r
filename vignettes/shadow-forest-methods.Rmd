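---
title: "Shadow-forest selection of treatment-sensitive OTUs: models and methods"
author: "shadowForest maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shadow-forest selection of treatment-sensitive OTUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A two-group feeding intervention (control diet vs a supplemented diet)
changes the composition of a gut microbial community, but 16S rRNA count
data make it hard to say *which* taxa respond: thousands of operational
taxonomic units (OTUs), an order of magnitude more features than samples,
heavy-tailed abundances, excess zeros, library-size nuisance variation,
and strong inter-individual and inter-trial variability. Classical
per-taxon tests ignore multivariate structure; naive random-forest
importance rankings have no null reference, so there is no principled
place to cut the ranked list.

`shadowForest` implements a shadow-feature extension of random-forest
variable importance that supplies that null reference, together with the
supporting stages a complete analysis needs: rarefaction, relative
abundance, taxonomic aggregation, multi-trial pooling, generalized
UniFrac beta diversity, principal-coordinates ordination, one-factor
PERMANOVA, and phylum-level reporting. A synthetic community generator
with planted treatment-sensitive OTUs provides ground truth for
validating every stage.

# The core method

## Shadow features

For each of the $p$ real OTU features a *shadow feature* is created by
permuting its values across samples (`makeShadowFeatures()`). A shadow
has exactly the marginal distribution of its parent but, by construction,
no association with the group label. A classification random forest is
fit on all $2p$ columns and every column receives a variable importance
metric (VIM): the out-of-bag permutation importance, i.e. the mean over
trees of the decrease in OOB accuracy when the feature is permuted among
the OOB samples. This is an absolute accuracy fraction, which is the
scale on which the default importance cut-off of 0.001 lives.

## Stability repetitions

A single fit confounds real signal with one arbitrary set of shadow
permutations. `stabilityVims()` therefore repeats the whole procedure
`nRepetitions` times (default 50), regenerating **every** shadow
permutation from a fresh sub-seed and refitting the forest, giving each
feature a distribution of importances across repetitions.

## The relevance likelihood

Within each repetition the highest importance reached by any shadow — the
*shadow envelope* — is the best score pure noise achieved on this dataset
in that refit. Because shadows are redrawn each repetition, the envelope
values are independent draws of that "best noise" statistic. Each real
feature's per-repetition importances are compared against the envelope
with a one-sided Welch $t$-test ($H_1$: the feature's mean importance
exceeds the envelope's); the *relevance likelihood* is $100(1-p)$. An OTU
is selected when its likelihood rounds to 100 at integer reporting
precision ($p \le 0.005$) **and** its mean importance is at least 0.001.
Judging every feature against the maximum over all shadows makes the gate
a family-wise control device, and no further multiplicity correction is
applied.

A design note on the reference. An alternative formulation identifies the
single shadow feature with the highest *mean* importance across
repetitions and uses that shadow's per-repetition values as the
reference. With fresh shadows per repetition this reference collapses:
averaging over independent permutations shrinks every individual shadow's
mean towards the null center, while a real feature's chance association
with the labels is a fixed property of the dataset that persists across
refits. In pure-null experiments (200 OTUs, 48 samples) the best real
features then tested significant against that weakened reference at $p$
down to $10^{-10}$, i.e. the gate controlled nothing. The envelope
reference — in the spirit of the Boruta family of algorithms from which
this approach descends — restores the intended control, and is the
package's default and only behaviour.

Even with the envelope the gate is not exact: the Welch test treats a
feature's across-repetition variance (forest noise only) as its sampling
noise, but the feature's chance association with the labels is fixed in
any finite dataset. In null simulations at 200 OTUs $\times$ 48 samples
roughly one dataset in ten yields a single false selection whose
association (the best of 200 features) persistently exceeds the envelope.
Users should read the selected set as "features that outperformed
everything noise achieved on this dataset", not as a per-dataset 5% FWER
guarantee; at the default study scale (500 OTUs, 96 samples) we observe
0–1 false selections alongside complete recovery of 4-fold planted
effects.

## Direction of change

Selected OTUs are annotated by the ratio of mean relative abundance in
treatment to control (`directionOfChange()`), with a pseudo-fraction —
half the smallest nonzero relative abundance in the table — added to both
means so OTUs absent from one group get a finite fold change. A ratio of
exactly 1 is reported as `unchanged` and excluded from both direction
counts in summaries.

# Supporting stages

**Rarefaction** (`rarefy()`) subsamples each sample without replacement
(multivariate hypergeometric) to a common depth; samples below the depth
are dropped and reported, never upsampled. The depth is a user decision —
the package deliberately has no default.

**Generalized UniFrac** (`generalizedUnifrac()`): for samples $A,B$ and
branch $i$ with length $b_i$ and descending read fractions $p_i^A,p_i^B$,

$$d^{(\alpha)}(A,B)=
\frac{\sum_i b_i\,(p_i^A+p_i^B)^{\alpha}\,
       \frac{|p_i^A-p_i^B|}{p_i^A+p_i^B}}
     {\sum_i b_i\,(p_i^A+p_i^B)^{\alpha}},$$

with branches carrying no reads from either sample contributing nothing.
$\alpha$ defaults to 0.5, the usual compromise between sensitivity to
abundant ($\alpha = 1$, the weighted-normalized UniFrac) and rare
lineages; it is exposed because reasonable analyses differ here. Branch
proportions come from a single postorder accumulation, and the
implementation is verified against a brute-force descendant-set oracle
and an independently coded weighted-normalized UniFrac in the test suite.

**Ordination** (`pcoa()`): distances are summarized by classical metric
scaling (principal coordinates). Ordination "PCA" on a distance matrix is
implemented as PCoA — the standard reading for UniFrac distances, exact
PCA when the distances are Euclidean. Negative eigenvalues are kept in
the result for inspection; their axes are discarded and `k` is truncated
with a warning when fewer positive axes exist.

**PERMANOVA** (`permanova()`): one-factor pseudo-$F$ from the
squared-distance partition, free label permutations (no strata), and the
add-one p-value convention $p = (1 + \#\{F^\ast \ge F\})/(1 + n_{perm})$
so $p > 0$ always. Calibration (uniform null p-values) and the minimal
attainable p on separated clusters are asserted in the tests.

**Aggregation, pooling, day filtering**: count-conserving operations over
a taxonomy and per-sample metadata; totals are property-tested to be
conserved on random tables.

# The synthetic community generator

`simulateCommunity()` emulates the multi-trial feeding-trial design the
package targets: by default 4 trials, 12 samples per group per trial at
day 35, and 500 OTUs — the scale reported for cecal communities.
Mechanics, in generation order:

1. **Baseline composition.** One log-normal abundance per OTU
   (`meanlog` 0, `sdlog` 1.5): a few dominant phylotypes over a long tail
   of rare taxa.
2. **Planted effects.** The first `nSensitive` OTUs are multiplied by
   their fold change (default 10 OTUs at 4 and 1/4, five each) in the
   treatment composition *before* renormalization, so planted increases
   mechanically depress all other taxa slightly — the compositional
   artefact real data carry. Planted OTUs take baselines at fixed
   quantiles 0.70–0.98 of the same log-normal rather than random draws: a
   diet-sensitive taxon is by construction an observable one, and an OTU
   whose expected depth is a fraction of a read could carry no
   recoverable signal (its empirical direction would be undefined).
3. **Trial effects.** Each trial perturbs every OTU's log-abundance by a
   normal offset (sd 0.2), emulating inter-trial variability.
4. **Sampling.** Each sample draws a library size uniformly from
   2,000–5,000 reads (a desk-scale stand-in for the roughly
   3,500 reads/sample of the motivating datasets), applies a per-entry
   zero-inflation mask (probability 0.05) to its composition, and
   resamples counts multinomially — so per-sample totals always respect
   the configured range.

All randomness descends from one master seed through documented
sub-streams (`deriveSeeds()`), so identical configurations reproduce
byte-identical tables and any sub-simulation can be replayed in
isolation.

`simulateStudy()` additionally anchors planted increased OTUs to phylum
Bacteroidetes and planted decreased OTUs to Firmicutes in the synthetic
taxonomy (the phylum-level shift pattern such studies report), and
attaches a random rooted binary phylogeny with uniform branch lengths.

What the generator does **not** emulate: sequencing error, chimeras,
over-dispersed (e.g. Dirichlet-multinomial) sampling beyond the planted
trial offsets, phylogenetic correlation between abundance and tree
position, or taxon-taxon interaction networks. Tests that pass on this
generator therefore demonstrate correctness of the algorithms and
calibration under idealized compositional noise — not performance on any
particular real dataset.

# Numerical and design choices

* **Forest engine.** The forests are standard classification random
  forests (`ranger`, single-threaded for reproducibility) with OOB
  permutation importance. The shadow/likelihood statistics are
  learner-agnostic; a conditional-inference forest could be substituted
  at the `fitForestVim()` interface without touching the rest.
* **Input scale.** Forests see per-sample relative abundances by default
  (library size is a nuisance); raw counts by flag.
* **Welch test.** Implemented in closed form (Welch–Satterthwaite
  degrees of freedom), unpaired, one-sided. Degenerate zero-variance
  pairs use the limiting convention: $p = 0$, $1$ or $0.5$ as the mean
  difference is positive, negative or zero.
* **Thresholds.** Likelihood 100 means "rounds to 100", i.e.
  $p \le 0.005$; the cut at exactly 100% is acknowledged as arbitrary and
  both gates are configuration, not constants.
* **Ties.** Results sort by mean importance descending, OTU id ascending;
  fold-change ties report `unchanged`.
* **Rarefaction depth, UniFrac $\alpha$, permutation count** are exposed
  parameters with documented defaults ($\alpha = 0.5$, 999 permutations)
  because the analyses the package supports legitimately vary them.
* **Problem sizes in the test suite.** Calibration and recovery tests run
  at 200–500 OTUs and 48–96 samples with 20–50 repetitions of 200–500
  trees — the scale at which the method's statistical properties are
  measurable while a full run of the suite stays comfortably
  interactive. The acceptance script runs the full default study
  (4 trials, 96 samples, 500 OTUs, 50 repetitions of 500 trees).

# Known limitations

* The shadow gate's family-wise control is approximate in finite
  samples (see above); expect occasional single false selections on
  null data at 48 samples.
* PERMANOVA is one-factor with free permutations; trial-stratified or
  nested designs are out of scope.
* The UniFrac implementation requires every OTU on the supplied rooted
  tree; it does not infer or root trees.
* Direction annotation is marginal (per-OTU mean ratio); it does not
  model the compositional coupling it inherits from the data.
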