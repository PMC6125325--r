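# shadowForest

Shadow-feature random-forest selection of treatment-sensitive OTUs in
microbiome count data.

## What problem it solves, and for whom

Feeding-trial microbiome studies ask which bacterial taxa respond to a
dietary intervention. The data — 16S rRNA OTU count tables — have an
order of magnitude more features than samples, heavy-tailed abundances,
excess zeros and library-size nuisance variation, so a ranked list of
random-forest importances by itself gives no principled place to cut.
`shadowForest` is for microbiome analysts who want a *null-referenced*
feature selection: every OTU competes against shadow features (permuted
copies of the real features that retain the marginal distribution but
destroy the label association), and only OTUs that reliably beat the best
the noise achieved are selected.

## The method

For a binary classification (control vs treatment), each of `p` OTU
features is augmented with a permuted shadow. A classification random
forest scores all `2p` columns with the out-of-bag permutation importance
(mean decrease in OOB accuracy). The fit is repeated `R` times (default
50) with **fresh shadow permutations each time**. In repetition `r`, the
highest importance over all shadows defines the *shadow envelope*
`s_r` — the best score pure noise achieved in that refit. For OTU `j`
with importances `v_j1 … v_jR` the relevance likelihood is

    L_j = 100 × (1 − p_j),   p_j = one-sided Welch t-test of
                             H1: mean(v_j·) > mean(s·)

and OTU `j` is selected when `L_j` rounds to 100 (`p_j ≤ 0.005`) **and**
its mean importance is ≥ 0.001. Selected OTUs are annotated with the
direction and magnitude of their abundance shift (fold change of group
mean relative abundances) and rolled up by phylum.

Supporting stages: rarefaction (multivariate hypergeometric), relative
abundance, taxonomic aggregation, multi-trial pooling, generalized
UniFrac

    d_α(A,B) = Σ_i b_i (p_iA+p_iB)^α |p_iA−p_iB|/(p_iA+p_iB)
             / Σ_i b_i (p_iA+p_iB)^α

over a rooted phylogeny, principal-coordinates ordination, and one-factor
PERMANOVA with the add-one permutation p-value. A synthetic community
generator plants treatment-sensitive OTUs with known direction so the
entire pipeline is validated against ground truth. See the methods
vignette (`vignettes/shadow-forest-methods.Rmd`) for models, assumptions
and design choices.

## Worked example

```r
library(shadowForest)

study <- simulateStudy(simulationConfig(seed = 1L))  # 4 trials, 10 planted OTUs
x <- filterToDay(study$experiment, 35)
x
#> OtuExperiment: 500 OTUs x 96 samples
#>   library sizes: 2048-4975 (median 3512)
#>   trial: T1(24) T2(24) T3(24) T4(24)
#>   day: 35(96)
#>   group: control(48) treatment(48)
#>   taxonomy: 10 phyla

res <- erfRelevance(x, erfConfig(nRepetitions = 20L, nTrees = 200L,
                                 seed = 42L))
res
#> ErfResult: 500 OTUs scored over 20 repetitions x 200 trees
#>   selected: 10 (5 increased, 5 decreased)
#>   top shadow reference: shadow__OTU_0389 (mean VIM 0.00017)

head(as.data.frame(relevanceTable(res))[, -2], 4)
#>            otu_id   mean_vim likelihood_pct selected direction fold_change
#> OTU_0010 OTU_0010 0.03445945            100     TRUE decreased   0.2365176
#> OTU_0005 OTU_0005 0.03166468            100     TRUE increased   3.8623910
#> OTU_0004 OTU_0004 0.03144061            100     TRUE increased   3.8587162
#> OTU_0007 OTU_0007 0.02855294            100     TRUE decreased   0.2355071
```

All 10 planted OTUs (4-fold effects, 5 up / 5 down) are selected with no
false positives; fold changes recover the planted 4 and 1/4 up to
compositional shrinkage. The phylum roll-up shows the planted
community-level shift — Bacteroidetes up, Firmicutes down:

```r
as.data.frame(phylumShift(x))[1:2, c("control_mean_pct",
                                     "treatment_mean_pct", "delta_pct")]
#>               control_mean_pct treatment_mean_pct delta_pct
#> Firmicutes           75.701678           72.47705 -3.224630
#> Bacteroidetes        11.788930           14.92840  3.139466
```

A shell entry point wrapping the same functions is installed at
`inst/scripts/otu-pipeline.R` (subcommands `simulate`, `rarefy`,
`aggregate`, `pool`, `filter`, `diversity`, `permanova`, `select`,
`report`; every run writes a JSON manifest with the full configuration
and derived seeds).

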