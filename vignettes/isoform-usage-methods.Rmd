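---
title: "Subtype-specific isoform usage: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype-specific isoform usage: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isousage)
```

## The problem

Estrogen-receptor-positive (ER+) and triple-negative (TN) breast tumours
differ not only in which genes they express, but in *which isoforms of the
same genes* they express. A gene can keep its total output constant while
switching between transcript variants that differ in promoter, splice
structure, or 3'UTR — with real consequences (the short CASP2 isoform, for
example, is anti-apoptotic). `isousage` implements the analysis that
detects such subtype-specific isoform usage from transcript-level
abundance matrices, classifies the structural mechanism behind each
differential isoform pair, transfers a subtype classifier to a NanoString
count platform, and quantifies overlap between knockdown-responsive and
subtype-specific isoform sets with exact contingency statistics.

## The interaction model

The central statistic is the subtype-by-isoform interaction. For one gene
with $L$ isoforms measured in $S$ samples, observations are stacked as
$(sample, isoform)$ rows and the fixed-effects linear model

$$ y = \mu + \beta_{subtype} + \beta_{isoform} + \beta_{subtype \times isoform} + \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2) $$

is compared to its no-interaction reduction by the extra-sum-of-squares
F-test on $(L-1,\; n-2L)$ degrees of freedom, $n = SL$. A significant
interaction means the *relative* abundance of the gene's isoforms depends
on subtype — isoform usage, as distinct from gene-level differential
expression (which the subtype main effect absorbs).

Three conventions matter:

* **Response scale.** All linear models run on $\log_2(\mathrm{FPKM}+1)$
  after quantile normalization. F-tests on raw FPKM are dominated by
  variance heterogeneity between high- and low-abundance transcripts;
  the offset of 1 keeps undetected transcripts at zero.
* **Independence caveat.** The stacked layout treats the $L$ measurements
  from one sample as independent, which they are not (they share library
  and biology). This is the stated model, kept for fidelity; it is why
  the interaction F is *not* exactly the squared paired-difference t
  statistic even in the balanced two-isoform case — the two share their
  numerator contrast but pool error differently. Calibration is instead
  demonstrated empirically: on 5,000 simulated null genes with the 11/14
  subtype split, the type-I error at $\alpha = 0.05$ lands in
  $[0.04, 0.06]$ and the null p-values pass a uniformity KS test.
* **Detection filter.** A transcript enters testing when detected
  (abundance > 0) in at least 2 samples.

Pairwise testing (`pairwise_interaction_tests`) restricts the model to
each unordered isoform pair ($L = 2$), where the single interaction
coefficient's sign is the direction: positive means the
lexicographically-larger isoform is relatively favoured in TN. q-values
are computed over all pairs jointly.

## Storey q-values

`storey_qvalues` estimates the null proportion as
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$ on the grid
$\lambda = 0.05, \dots, 0.95$, smooths with a cubic polynomial in
$\lambda$ (dependency-free and stable on a 19-point grid; a natural
spline differs negligibly here), evaluates at $\lambda = 0.95$, and
clamps to $(0, 1]$. Then $q(p_{(i)}) = \min_{j \ge i} \hat\pi_0\, m\,
p_{(j)}/j$. With $\pi_0 = 1$ this is exactly Benjamini–Hochberg, which
the test suite asserts on every run; with fewer than 20 p-values the
estimator is unreliable and the implementation falls back to
$\pi_0 = 1$ with a warning.

## Structural classification of isoform pairs

`compare_pair` labels each transcript's exonic bases 5'UTR / CDS / 3'UTR
using its own CDS, strand-aware, and takes the symmetric difference of
the two exonic base sets. The mutually exclusive `primary_category`
follows a priority rule — internal-exon difference → `alt_splicing`,
else 5'UTR difference → `alt_promoter`, else `alt_3utr` — because a pair
may differ in several regions at once and splicing is the dominant and
most interpretable class. "Internal-exon difference" means CDS-labeled
differing bases *or* differing internal splice structure, so a skipped
exon lying wholly in a UTR still counts as splicing, while pure
terminal-exon-length differences fall to the UTR categories. Transcripts
without a CDS make UTR labels meaningless; such pairs are classified by
splice structure only and flagged `no_cds`.

`call_splice_events` resolves internal differences with a bubble
algorithm: within the overlap of the two spans, regions bounded by
splice positions common to both transcripts (kind-matched: exon start
with exon start, exon end with exon end) are classified independently —
an intron of one isoform strictly inside an exon of the other is
`intron_retention`; a single intron of one isoform bridging a bubble in
which the other has one exon with flanking introns is `exon_skipping`;
two introns sharing their acceptor but not their donor are `alt_donor`
(and vice versa), with donor/acceptor orientation strand-aware (plus
strand: donor = intron start). Distinct, non-overlapping first or last
exons in transcription direction give `alt_first_exon` /
`alt_last_exon`. Anything matching no single taxon — mutually exclusive
exons, multi-exon skips — is emitted as `complex` and excluded from the
four-way fractions rather than silently misclassified. Event fractions
are counted per pair-event occurrence (a recurring genomic event in
several pairs counts each time), matching how pairs are tested.

## NanoString normalization and the platform transfer

Probe counts are normalized by a log-link negative-binomial regression
with terms for assay (cartridge), well, log median negative-control
count, log median housekeeping count, and probe identity; dispersion
$\theta$ is estimated by maximum likelihood alternating with the IRLS
updates. The control covariates enter with free slopes rather than fixed
offsets. Downstream analysis uses Pearson residuals,
$(y - \hat\mu)/\sqrt{\hat\mu + \hat\mu^2/\theta}$ — scale-stabilized and
standard for NB models; deviance residuals are available behind a flag.
Note that $\theta$ here absorbs *all* variation the design does not
model: on real tumour panels, biological sample-to-sample variation
deflates $\hat\theta$ well below the purely technical dispersion. The
recovery check therefore uses biologically flat, technically varying
input, where $\theta = 10$ is recovered within $[8, 12]$ from ~10k
observations.

The subtype classifier is an L2-penalized logistic regression fitted by
Newton/IRLS from a zero start (deterministic), with the penalty
excluding the intercept and features standardized internally. The
default strength of 1.0 is not innocuous: with ~200 features and ~25
samples the classes are linearly separable and the unpenalized MLE
diverges, so some regularization is a necessity, not a tuning choice.
ROC curves sweep all distinct scores; the trapezoid AUC is
cross-checked against the rank (Mann–Whitney) form, to which it is
identical.

## Exact overlap statistics

All 2×2 machinery uses the probability-mass two-sided Fisher convention
(sum of hypergeometric probabilities not exceeding the observed table's,
evaluated in log space so p-values below $10^{-30}$ are computed without
underflow) and the cross-product odds ratio $ad/bc$ — both verified
against published knockdown-overlap statistics at printed precision, and
the Fisher p against brute-force enumeration over all margin-preserving
tables. Confidence intervals use the Woolf logit method with the
Haldane–Anscombe 0.5 correction when a cell is zero (applied to the CI
only; the point estimate may be 0 or $\infty$). The universe of an
overlap table must always be supplied explicitly — the $d$ cell, and
with it the odds ratio, depends on it, and published per-factor tables
demonstrably use different universes. Binding-site overlap uses a
default window of 25 kb either side of the gene span (configurable).

## What the synthetic-data generator emulates

`sim_config` defaults encode the study conditions: 11 ER+ and 14 TN
samples; a RefSeq-like isoform-count distribution (~24% multi-isoform
genes); multi-isoform gene models derived from a base transcript by
exon skipping, intron retention, donor/acceptor shifts, or alternative
first/last exons, with the default variant mix following the event
fractions observed among differential pairs in breast tumours; planted
log2 switch effects of 2 with residual noise 0.5; NanoString counts with
$\theta = 10$ and assay/well/library factors; knockdown responses as
biological duplicates opposing the subtype direction with probability
`kd_concordance`; and binding sites planted with an odds multiplier near
knockdown-responsive genes. Genes are laid out 100 kb apart on one
synthetic chromosome so that 25 kb binding windows of neighbouring genes
do not overlap.

Randomness is organised as per-gene substreams keyed by (seed, stream,
gene index): changing one configuration field, or growing `n_genes`,
never re-randomizes unrelated genes, and all outputs are byte-identical
under a fixed seed. Cohort biology (baselines, DE flags, switch
assignments) is keyed only by the seed and gene, while residual noise is
additionally keyed by a cohort index — `simulate_cohort(models, cfg,
cohort = 2)` is a replication cohort with the same planted truth and new
samples, which is what makes cross-cohort classifier transfer a
meaningful check (AUC $\ge$ 0.9 under the default switch conditions).

The generator does *not* model read-level effects (no FASTQ, no
fragment-length or positional bias), within-sample correlation between
isoforms, batch structure beyond assay/well factors, or isoform-count
distributions conditioned on gene length. Passing tests therefore show
that the statistical machinery is correct and calibrated under the
stated generative model — not that real tumour data satisfy that model.

## The concordance emulation

Cross-platform concordance compares, per isoform pair and sample, the
sign of $\log_2((\mathrm{FPKM}_A+1)/(\mathrm{FPKM}_B+1))$ with the sign
of the NanoString residual difference. Because the NB normalization
removes each probe's mean, a pair whose two isoforms differ strongly in
baseline abundance has an RNA-seq ratio of constant sign but a
NanoString value centred at zero — such pairs are *systematically*
discordant across most samples, which is exactly the behaviour reported
for real panels. `concordance_panel_config` therefore emulates a panel
designed from significant pairs with comparable within-pair abundance
(`iso_offset_sd = 0.25`) and tumour-scale biological heterogeneity
(`noise_sd = 1.75`) shared by both platforms; under these frozen
conditions mean per-sample concordance lands in the 80–85% band. The
band is a property of the emulation conditions, chosen once; it is not a
free parameter of the analysis functions.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; GTF (1-based
  closed) conversion happens only at I/O boundaries, BED needs none.
* Genes are grouped by exact `gene_id` string match; no
  coordinate-overlap regrouping.
* The CDS is a single genomic span per transcript; stop-codon inclusion
  conventions do not move differences across region labels at event
  granularity, so no correction is applied.
* A zero-residual interaction fit reports $F = 0, p = 1$ when the
  interaction sum of squares is also zero, and $F = \infty, p = 0$
  otherwise.
* Wilcoxon tests are exact for combined $n \le 25$ without ties,
  otherwise normal approximation with tie and continuity correction;
  constant rows get $p = 1$.
* Quantile normalization resolves ties as the mean of the reference
  order statistics they span (deterministic under zero inflation), so
  tied columns may deviate from the shared sorted vector at tied ranks
  only.
* PCA signs follow a fixed rule (largest-magnitude loading of each
  component is positive); only mean centering, no variance scaling.

## Problem sizes used by the checks

The statistical checks run at sizes chosen to make Monte-Carlo error
small relative to the asserted bands: 5,000 null genes for type-I error
calibration; 2,000 genes (~600 planted switches) for recall and
binding-enrichment recovery; ~10,000 observations for dispersion
recovery and $\pi_0$ estimation; 500 generated pairs for the
strand-covariance property; 200 random tables for the Fisher
enumeration oracle; 1,000 random score sets for the AUC identity.

## Known limitations

* The interaction model ignores within-sample isoform correlation
  (fixed-effects OLS), inflating or deflating power depending on the
  true correlation structure; a mixed or GLS formulation is out of
  scope.
* Event classification is pairwise; a gene-level event graph
  (transcript-set bubbles) would deduplicate recurring events across
  pairs.
* UTR/CDS classification is at event granularity and does not predict
  protein consequences.
* The NB normalization assumes probe-wise means stable across samples
  apart from modelled technical terms; strong biological structure
  loads onto $\theta$.
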