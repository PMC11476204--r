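---
title: "Methods: heart-specific discovery of splice-disrupting variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-specific discovery of splice-disrupting variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most children with congenital heart disease (CHD) leave clinical genetic
testing without a molecular diagnosis. One underexplored reservoir of
missed diagnoses is the non-canonical splice-disrupting variant: a DNA
change that creates or destroys an exon boundary without touching the
GT/AG dinucleotides that panels and exomes interrogate. Sequence-based
predictors (SpliceAI-style delta scores) flag such variants genome-wide,
but they know nothing about which genes and isoforms are actually
expressed and spliced in myocardium, so their genome-wide precision is
poor at the permissive thresholds needed for sensitivity.

`cardiosplice` implements a tissue-informed discovery design. In a
*discovery* cohort with both genome sequencing (GS) and myocardial
RNA-Seq, candidate variants (delta >= 0.2, internally rare) are labeled
by whether the same patient's myocardium shows a significant aberrant
splicing event near the variant. Those labels train a random forest that
combines the sequence-level score with DNA context features and
myocardial expression. The trained model is then applied to GS-only
cohorts, and carriers of model-selected, population-rare variants in
disease genes are compared between cases and controls.

Because the real cohorts are controlled-access, the package ships a
synthetic cohort generator that reproduces the *statistical structure*
the analysis depends on, with latent causal truth, so every stage is
testable end to end.

## Splice metrics and the outlier null

From split-read counts we compute, per sample:

* **psi5** of a junction: its split reads over all split reads sharing
  the same donor (alternative acceptor usage seen from the 5' side);
* **psi3**: the symmetric quantity over shared acceptors;
* **theta** of a splice site: split / (split + nonsplit), a splicing
  efficiency that drops under intron retention.

Sites are first filtered to those with at least 15 reads in at least one
sample. For each retained site the cohort null is a beta-binomial fitted
by method of moments to the per-sample proportions k/n: alpha and beta
are chosen so the Beta mean and variance equal the sample mean and
variance of k/n. Two conventions matter:

* **Leave-one-out everywhere.** The expected psi for sample *s* is the
  count-weighted mean over all *other* samples,
  `(sum k - k_s) / (sum n - n_s)`, and the moments used for sample *s*'s
  p-value likewise exclude *s*. Without this, a strong outlier inflates
  the variance of its own null and masks itself; with it, the null
  describes the cohort the sample is being compared against.
* **Thresholded decision rule.** An event is significant iff FDR < 0.2
  (Benjamini-Hochberg within each sample across its tested sites),
  |Z| >= 1 (Z on `logit((k+1)/(n+2))`, standardized by the site's cohort
  mean and SD), |delta psi| >= 0.2, and the expected psi is <= 0.1 or
  >= 0.9. The last condition restricts calling to near-constitutive or
  near-unused sites, where a 0.2 shift is interpretable; sites with
  intermediate baseline usage (common alternative splicing) are
  uninformative and excluded. Events mapping to no gene or to more than
  one gene are dropped.

Numerical choices: p-values are two-sided by doubling the smaller
beta-binomial tail, capped at 1, with the shorter tail summed exactly
and the other obtained by complement. When the sample variance is zero
or exceeds the Bernoulli bound the concentration is clamped (to 1e6,
i.e. a near-degenerate Beta); sites with fewer than 3 informative
samples are skipped; p-value ties are broken by metric and coordinate
order so output is deterministic. The replacement of a latent-factor
denoising model by this per-site cohort null is a deliberate design
choice: it is dependency-free, exactly reproducible, and preserves the
decision rule, at the cost of not absorbing technical covariation
between samples (see Limitations).

The within-sample BH correction is applied across all tested sites of
all three metrics pooled, since downstream steps consume the three
metrics as one event stream. The Z-score is computed on the logit scale
(the |Z| >= 1 rule needs a scale, and logit stabilizes boundary psi);
the alternative natural-scale convention would change individual Z
values but not the leave-one-out expectations or p-values.

## Expression outliers and the NMD check

Genes are retained when at least 10 reads are seen in strictly more than
half the samples. Counts are normalized by median-of-ratios size factors
(genes with a zero geometric mean excluded from the reference), and
per-gene Z-scores are computed on `log2(normalized + 1)`. This is a
deterministic stand-in for autoencoder-based expression outlier callers;
only the Z-scores are consumed downstream. The nonsense-mediated-decay
(NMD) check compares carrier-sample Z-scores of genes holding
model-selected vs model-rejected variants with a Welch two-sided t-test:
true splice disruption should drag expression down.

## Screening, labeling, features

Variants enter the candidate pool when the maximum of the four delta
scores (acceptor/donor gain/loss) is >= 0.2 (inclusive), the call is
PASS, and the variant is carried by at most one sample. The carrier-count
form implements internal rarity uniformly across cohort sizes (it equals
MAF < 0.01 at n ~ 100 and MAF < 0.03 at n ~ 48). Population rarity
additionally requires both gnomAD v2 and v3 PopMax frequencies below
1e-4; missing frequencies count as absent (0) and are tallied for audit.

A screened variant in the discovery cohort is labeled **confirmed** when
a significant splicing event exists in the same gene and carrier sample
with a boundary (donor or acceptor) within 100 bp of the variant
(inclusive at exactly 100); **indeterminate** when events exist in the
gene and sample only beyond the window (excluded from all training and
evaluation); otherwise **unconfirmed**. Only variants carried by
RNA-profiled samples are labeled: a label for a genome-only carrier
would be unfalsifiable. Significant events in disease genes with no
candidate variant within the window are reported as orphans and never
train the model.

Model features: `max_delta`; `dist_junction` (minimal absolute distance
to any annotated junction endpoint of the gene, leftmost reference
position for indels); `is_snv`; branchpoint / low-complexity / repeat
flags; `median_tpm` (discovery-cohort median). Missing values are never
imputed; rows with a missing value in the active feature set are
omitted and counted.

## The four models and imbalance handling

The four feature sets are nested comparisons, not competitors tuned per
set: (1) `max_delta` only; (2) DNA context without delta scores;
(3) DNA context + `median_tpm`; (4) everything. Each is a probability
random forest (500 trees, per-node feature subsampling, `ranger`
backend) whose score is the mean tree probability, thresholded at 0.5
by default (the operating point is configurable; no calibration is
attempted).

Confirmed variants are rare (~1 in 80 screened), so two imbalance
treatments are provided. **Weighted**: each observation enters the
per-tree bootstrap with weight inversely proportional to its class
count, so trees see class-balanced resamples — this moves the
probability scale and is what gives the weighted models their higher
sensitivity at the default threshold. **SMOTE**: the minority class is
oversampled to parity by interpolating between a minority point and one
of its k = 5 nearest minority neighbors (Euclidean distance on
standardized continuous features); binary features are copied from the
nearer parent, since interpolation is undefined for them.

Evaluation is stratified five-fold cross-validation with SMOTE/weights
applied strictly inside training folds; pooled metrics come from the
concatenated out-of-fold scores, and the final model is refit on all
labeled data before application elsewhere. Metrics: AUC as the
normalized rank (Mann-Whitney) statistic with ties averaged; sensitivity
and specificity at the vote threshold; the Haldane-Anscombe odds ratio
`((TP+.5)(TN+.5))/((FP+.5)(FN+.5))`, finite for any table; and a
two-sided Fisher exact p on the uncorrected confusion table. A
bias-variance decomposition over bootstrap refits reports, per held-out
point, `mse = bias^2 + variance` exactly (the covariance term of the
full three-way decomposition is out of scope).

## Prioritization and burden

Selected variants are classified by position relative to the gene model
(intronic offsets 1-2: canonical splice site; intronic 3-8 or exonic
1-3: splice region; exonic > 3: exonic; intronic 9-10: proximal;
intronic > 10: deep intronic — five classes that partition every
in-gene base, with the 9-10 bucket making the "> 10 bp" convention for
deep-intronic exact) and by predicted effect (loss if max of the loss
pair >= 0.2, gain if max of the gain pair >= 0.2; both thresholds reuse
the screening cut). Reportability: Tier 1 genes with dominant
inheritance (any genotype) or recessive inheritance with a homozygous
carrier; Tier 2 genes with pLI >= 0.9.

Burden first runs a technical control: per-sample counts of rare
synonymous variants compared between cohorts by a two-sided
Mann-Whitney U test (a shift here indicates platform artefacts, not
biology). The carrier burden then compares, per stratum, the number of
samples harboring at least one qualifying variant: Fisher's exact test
on the raw 2x2 counts, with the odds ratio and Wald 95% CI
(`exp(log OR +- 1.96 sqrt(sum 1/(cell+0.5)))`) computed on
Haldane-Anscombe corrected cells. The correction applies to the OR/CI
only, never to the test.

## The synthetic cohort generator

The generator emulates the joint structure the analysis assumes, not
sequencing reads:

* **Gene models**: 300 genes by default, each on its own synthetic
  chromosome (+ strand, 1-based inclusive), 4-8 exons, annotated
  junctions from adjacent exon pairs; 10% Tier 1 (with AD/AR
  inheritance), 30% Tier 2; bimodal pLI so constrained and
  unconstrained Tier 2 genes both exist.
* **Expression**: per-gene baselines `N(mu = 1.5, sd = 1.5)` on the
  natural-log scale with per-sample noise sd 0.25; a realistic minority
  of genes falls below median TPM 1 and exercises the expression
  filter. Gene counts are negative binomial with mean 50 x TPM.
* **Junction counts**: negative binomial split reads with mean scaling
  with the gene's TPM (80 per junction at the typical expression
  level); 15% of donors carry a competing alternative junction, half
  with substantial minor-isoform share (these sit in the excluded
  0.1-0.9 expected-psi band and exercise that rule) and half with a
  small share. Each annotated junction has a site-level (split,
  nonsplit) pair with 1-6% baseline intron retention.
* **Variants**: a Poisson number per sample (default 80) that have, by
  construction, already passed the delta >= 0.2 screen; max delta
  `0.2 + 0.8 Beta(0.7, 4)`; the non-maximal channels are scaled down by
  `Beta(1, 4)` so most variants predict a single effect. Region flags
  are independent Bernoulli (branchpoint 2%, low complexity 8%, repeat
  25%); 10% indels; 3% non-PASS; 2% second carriers; gnomAD
  frequencies mostly absent with a common slice to exercise the
  population-rarity filter.
* **Latent causality** is a logistic function of exactly three
  features — max delta, log median TPM, repeat flag — with frozen
  coefficients (-10, 10, 0.8, -1.5). This is the minimal model that
  reproduces the three univariable enrichments the analysis relies on
  (higher delta scores and expression, fewer repeat-region hits among
  confirmed variants); all other features are uninformative by
  construction, which keeps recovery tests interpretable. The
  coefficients were fixed once so the default cohort matches the
  intended study conditions — roughly one causal variant per 80
  screened and a latent-truth separability (Bayes AUC ~ 0.9) consistent
  with a well-powered discovery design — and are not revisited.
* **Planted effects**: each causal variant carried by an RNA-profiled
  sample perturbs its carrier only. Gain-type variants create a cryptic
  junction whose acceptor is the variant position, re-allocating
  `delta psi = 0.4` of the donor's split reads to it (per-donor totals
  conserved); loss-type variants re-allocate site reads from split to
  nonsplit, lowering theta by the same amount (site totals conserved).
  Shifts that would cross a boundary are clipped and recorded. Causal
  loss variants are placed within 40 bp of their junction and gain
  variants inside the target intron, mirroring where such variants act.
* **NMD**: the carrier's gene count is scaled by
  `2^(nmd_shift x sd_g)` (default shift -0.2 on the Z scale) so the
  expression module detects it without special-casing.
* **Case excess**: cases optionally receive extra causal variants in
  reportable Tier 1/2 genes at a configurable Poisson rate;
  `excess_rate_for_or()` converts a target carrier odds ratio into that
  rate given the baseline qualifying rate.

Identical configurations (including seed) yield byte-identical cohorts;
all randomness flows through one seeded stream.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: read-level artefacts (mapping errors,
homologous-gene cross-alignment of the kind that produces recurrent
false outliers in paralogous sarcomeric genes), correlated technical
covariation between samples (batch, library preparation) that
latent-factor models exist to absorb, linkage between variants,
multi-isoform gene structure, ancestry structure, and any sequence
content. The causal model is exactly the logistic form the features can
express, so model-recovery results are an upper bound on what real,
messier biology would give.

## Problem sizes used by the tests

The default generator (100 RNA-profiled cases, 250 genome-only
controls, 300 genes, ~80 variants/sample) is used for the seed-swept
model comparisons (10 seeds) and held-out validation (48-sample
cohorts). Null-calibration checks use deliberately smaller cohorts
(25-30 samples, 60-80 genes) so that hundreds of replicates stay cheap,
and the burden analyses use genome-only variant tables at the full
947 / 2570 cohort sizes with a sparse qualifying-variant density (one
screened variant per sample), which matches a realistic ~13% carrier
rate in controls. These sizes are the package's chosen operating points
for its own verification, stated here so results are interpreted at the
scale that produced them.

## Known limitations

* The cohort null does not correct latent confounders; on real RNA-Seq
  it will over-call outliers in the presence of batch structure.
* The expected-psi boundary rule discards genuinely aberrant events at
  sites with intermediate baseline usage, by design.
* Single-transcript gene models: junction distance uses one canonical
  model per gene, not per-isoform annotations.
* The effect classifier's symmetric >= 0.2 rule is a deterministic
  stand-in for ranking "the most probable predicted effect" when gain
  and loss scores are close.
* No hyperparameter search, probability calibration, or
  ancestry/relatedness handling.
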