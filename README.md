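# isousage

Differential transcript **isoform usage** between breast-cancer subtypes.

Estrogen-receptor-positive (ER+) and triple-negative (TN) breast tumours
are distinguishable not only by which genes they express but by *which
isoforms of the same genes* they express — through alternative promoter
usage, alternative splicing, and alternative 3'UTR usage. `isousage` is
an R package for analysts working with transcript-level abundance
matrices (FPKM-like, transcripts × samples) and gene models (GTF) who
want to detect, classify, and validate such subtype-specific isoform
switches.

## What it computes

**Interaction ANOVA.** For each multi-isoform gene, observations are
stacked as (sample, isoform) rows and the fixed-effects model

```
y ~ m0 + subtype + isoform + subtype:isoform + E
```

is compared against its no-interaction reduction by an
extra-sum-of-squares F-test on (L−1, n−2L) degrees of freedom. A
significant subtype×isoform interaction flags subtype-dependent isoform
usage, distinct from gene-level differential expression (Wilcoxon
rank-sum and per-gene linear models are also provided). Multiple testing
is controlled with Storey q-values (π₀ estimated on a λ grid with cubic
smoothing; exactly Benjamini–Hochberg when π₀ = 1).

**Structural classification.** Each differential isoform pair is
partitioned into alternative splicing / alternative promoter /
alternative 3'UTR by strand-aware 5'UTR–CDS–3'UTR base labeling, and its
splice events are called with a bubble algorithm: exon skipping, intron
retention, alternative donor, alternative acceptor (donor = intron start
on the + strand, reversed on −), plus alternative first/last exons at
the termini and an explicit `complex` bucket for anything that matches
no single taxon.

**Platform transfer.** NanoString-style probe counts are normalized with
a log-link negative-binomial model (terms for assay, well, log median
negative control, log median housekeeping, probe identity; θ estimated
by alternating ML) and analysed as Pearson residuals; isoform-ratio sign
concordance between platforms and an L2-penalized logistic subtype
classifier with ROC/AUC complete the replication machinery.

**Exact overlap statistics.** 2×2 contingency machinery for
knockdown-vs-subtype isoform overlap: two-sided Fisher exact tests
(probability-mass convention, log-space sums stable below 10⁻³⁰),
cross-product odds ratios with Woolf CIs, direction-concordance tables,
and binding-site overlap with an explicit universe and configurable
window.

**Synthetic data with ground truth.** A fully seeded generator emulates
the entire study: multi-isoform gene models with known planted variants,
an 11 ER+ / 14 TN cohort with planted switches, overdispersed probe
counts with assay/well effects, knockdown duplicates with tunable
concordance, and binding tracks with planted enrichment — so every
stage is testable without any external data.

## Worked example

```r
library(isousage)

cfg    <- sim_config(seed = 19, n_genes = 500,
                     isoform_count_distribution = c("2" = 1),
                     switch_fraction = 0.3, switch_effect = 2, noise_sd = 0.5)
models <- simulate_gene_models(cfg)
cohort <- simulate_cohort(models, cfg)

norm  <- log2p1(quantile_normalize(cohort$expression))
pairs <- pairwise_interaction_tests(norm, models, cohort$annotations)
head(pairs[order(pairs$q), ], 5)
#>     gene_id     iso_a     iso_b     F        p        q  beta direction
#> 417  g00417 g00417.t1 g00417.t2 118.7 2.50e-14 7.25e-12 -3.06        -1
#> 230  g00230 g00230.t1 g00230.t2 106.8 1.41e-13 2.04e-11  2.18         1
#> 447  g00447 g00447.t1 g00447.t2 102.3 2.82e-13 2.73e-11  1.75         1
#> 309  g00309 g00309.t1 g00309.t2  98.5 5.13e-13 3.72e-11  1.80         1
#> 304  g00304 g00304.t1 g00304.t2  93.0 1.27e-12 6.36e-11  2.30         1
```

Each row is one isoform pair: the interaction F and its p/q-value, and
the interaction coefficient `beta` whose sign says which isoform is
favoured in TN tumours (positive: `iso_b` relatively up in TN). Of the
planted switches, 96.6% are recovered at q < 0.05 here.

```r
sm <- summarize_pairs(pairs, models, fdr = 0.05)
sm$category_fractions
#> alt_splicing alt_promoter     alt_3utr
#>        0.860        0.098        0.043
sm$event_fractions
#>    exon_skipping intron_retention        alt_donor     alt_acceptor
#>            0.623            0.088            0.061            0.228
```

The 164 differential pairs partition into the three mechanism
categories, and their splice events into the four-way taxonomy; an
inclusion table counts, for each skipping/retention event, which subtype
favours the isoform carrying the extra sequence.

```r
overlap_result(contingency_2x2(63, 606, 275, 4243))
#> OverlapResult: OR = 1.6 (95% CI 1.2-2.14), Fisher p = 0.00183
```

— the exact contingency machinery applied to a published
knockdown-vs-subtype isoform overlap table (63 of 669 subtype-specific
isoforms also respond to MAGOH knockdown, universe 5,187).

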