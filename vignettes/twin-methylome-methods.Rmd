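---
title: "Methods: within-pair differential methylation in discordant MZ twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-pair differential methylation in discordant MZ twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
library(dplyr)
```

## The design

Monozygotic twins discordant for a phenotype are a natural experiment:
the co-twins share genotype, sex, age and most early environment, so a
methylation difference between them at a CpG is a candidate epigenetic
correlate of the phenotype rather than of genetic background. `twinmeth`
implements the whole-genome bisulfite sequencing (WGBS) version of this
analysis for cohorts of (affected, unaffected) twin pairs: CpG-level
quality control, threshold-based calling of differentially methylated
sites (DMS) and regions (DMRs) within each pair, interval annotation and
over-representation testing, and twin-similarity statistics. A
synthetic-cohort generator with planted ground truth makes every stage
testable end to end without access to human data.

## CpG-level quality control

Counts enter as Bismark-style cytosine reports or coverage files; the two
strands of a CpG dyad are collapsed into one record anchored at the
plus-strand cytosine. Three per-site filters follow, each a pure
predicate on a site, so the retained set is independent of the order of
application:

* **Joint coverage.** A site is kept only when *every* sample in the
  cohort has dyad depth of at least `min_reads` (default 20). This is the
  conservative reading of a common-site rule: all downstream
  within-pair and cross-pair comparisons then operate on one shared site
  set. The price is steep — at a mean depth of 30x, between a quarter and
  a third of sites fail a 20-read floor in at least one of twelve
  samples — and this is the dominant loss in the pipeline.
* **Strand concordance.** A dyad whose two strands disagree in
  methylation level by strictly more than `max_strand_delta` (default
  0.20) in any sample is removed everywhere. A strand with zero reads
  cannot be judged; such dyads are kept and flagged in the QC report.
  At 15 reads per strand this filter is noisy: a truly
  intermediate-methylation CpG (beta near 0.5) is removed with
  probability around 0.27 by sampling alone. That behaviour shapes the
  retained landscape toward well-determined, extreme-methylation sites,
  and it is the reason the simulator treats strand concordance specially
  at planted sites (below).
* **Blacklist.** Sites inside user-supplied intervals (artifact-prone
  regions) are removed. All interval files use BED convention (0-based,
  half-open); CpG positions are 1-based, and the single conversion rule
  — a position `p` is inside `(start, end]` — lives in one internal
  function.

Strict inequalities are used for every threshold in the package
(`> 0.20`, `> 0.30`, `< 0.25`, …), with a `1e-9` guard so that floating
point representation (`0.8 - 0.6 > 0.2`) cannot flip a boundary case.
Bisulfite conversion efficiency is estimated from an unmethylated
lambda-phage spike-in as converted / total cytosine reads; it is reported
in QC and not used as a filter by default.

## DMS calling

For each pair and retained site, the within-pair difference is
`delta = beta_affected - beta_unaffected` (negative = hypomethylated in
the affected twin). A site is a DMS for a pair when

1. `|delta| > 0.30`, and
2. the coefficient of variation of the *unaffected* individuals' beta
   values at that site is `< 0.25`.

The CV gate restricts calls to sites whose methylation is tightly
preserved among unaffected individuals, the compartment where a large
within-pair difference is most plausibly regulatory rather than
polymorphic. Two estimator choices were open and are exposed as
switches, with these defaults: the CV uses the sample (n−1) standard
deviation, and it is computed over all unaffected co-twins including the
pair under test (`cv_leave_out = TRUE` excludes it). M-values use base-2
logits (`m_value(0.5) = 0`), the convention of methylation array
statistics; the transform clamps beta to `[eps, 1-eps]` so boundaries
stay finite.

## DMR construction

Regions are built from per-site within-pair differences under four
rules: at least 3 member CpGs, each with `|delta| > 0.20`, all sharing
one direction, consecutive members at most 2 kb apart, and a region-mean
`|delta| > 0.25`. Two rule details were genuinely open:

* **Gap semantics.** "Within 2 kb" is read as a cap on the gap between
  *consecutive member CpGs*, not on the total span: published
  region tables in this design routinely contain 25+ CpGs over spans
  well beyond 2 kb, which a span cap could not produce.
* **Interleaved non-qualifying CpGs.** By default they are transparent:
  a CpG between two members that fails the 20% cut does not break the
  region (an opposite-direction *qualifying* CpG always does). The
  strictest alternative — any interleaved non-qualifying CpG breaks the
  run — is available as `strict_contiguity = TRUE`. The default was
  chosen on statistical grounds: at 30x depth a site with a true
  difference of 0.40 still fails the 0.20 cut about 2% of the time from
  sampling alone, so strict contiguity makes a genuine 5-site region
  unrecoverable whenever its interior site blinks, and long regions
  nearly impossible — inconsistent with the many-CpG regions such
  analyses report.

Before differencing, per-sample beta values pass through an
empirical-Bayes beta-binomial shrinkage: a method-of-moments beta prior
is fitted to each sample's landscape, rescaled to a total of
`shrinkage_strength` pseudo-counts (default 2), and the per-site
posterior mean `(m + a)/(m + u + a + b)` replaces the raw ratio. This is
a documented stand-in for the fully Bayesian regional models used in
this literature, whose internals are not reproducible from their
descriptions; it preserves their stabilising role (pulling low-depth
sites toward the sample's landscape) while keeping the stated regional
rules exact. Strength 0 recovers raw beta values, and with it the DMR
stage's per-site differences equal the DMS stage's exactly.

A group-wise variant replaces the within-pair difference with
(mean of affected) − (mean of unaffected) and applies identical rules.

## Annotation and enrichment

Hits are joined to the two nearest genes by unsigned TSS distance
(containment in a transcript counts as distance 0; ties break by TSS
coordinate then name), given a signed TSS distance in kb (negative =
upstream in the gene's orientation), and classified as `Prom` /
`In` / `IGR`. The promoter window is −2500..+500 bp around the TSS; that
window is the narrowest round choice consistent with classifying a hit
2 kb upstream as promoter while one 3 kb upstream is intergenic, and it
is configurable. Candidate-gene over-representation uses the one-sided
hypergeometric tail with the universe defined as genes carrying at least
one retained CpG — the standard over-representation framework, chosen
because the analysis needs "more than expected by chance" against the
testable universe, not the whole genome.

## Twin-similarity statistics

Per-pair Pearson correlations over the shared site set are summarised by
relationship (co-twin, and the three unrelated combinations);
`mask_intervals()` removes or isolates variably methylated regions
(VMRs); `abs_diff_profile()` gives per-site mean absolute differences
for a relationship, and the co-twin and unrelated profiles are compared
with a two-sample Kolmogorov–Smirnov test (asymptotic p by default,
exact behind a flag). Pearson rather than rank correlation is used for
inter-sample similarity, matching practice for methylome-wide
comparisons; platform concordance reports Pearson r and the fraction of
shared loci with `|delta beta| < 0.2` (strict).

## The synthetic cohort generator

`sim_config()` defaults describe the study conditions the package is
validated under: 6 male MZ pairs (one affected, one unaffected each),
50,000 CpGs on one synthetic chromosome at ~100 bp mean spacing, dyad
depth negative-binomial with mean 30 and size 100, and an unmethylated
lambda spike-in of 10,000 cytosines at true conversion 0.98.

The landscape model works on the logit scale and then draws stranded
binomial counts:

* **Baselines** come from a two-component beta mixture: 75% of sites
  from a methylated component (mean 0.97, concentration 300) and 25%
  from an unmethylated one (mean 0.03, concentration 120). This gives
  the strongly bimodal, majority-methylated landscape of real WGBS after
  the filters above; most retained CpGs are > 50% methylated.
* **Pair effects**: each twin pair shifts each site by a shared
  truncated-normal logit effect (sd 0.9, truncated at 1.5 sd). Sharing
  within the pair is what makes co-twins more correlated than unrelated
  individuals; truncation keeps pair shifts from smearing the bimodal
  landscape into the intermediate range where binomial noise would
  otherwise dominate.
* **Individual residuals**: logit sd 0.1 per sample.
* **VMR blocks**: 12% of sites lie in blocks of 40 consecutive CpGs.
  VMR baselines are drawn evenly from both mixture components, and each
  individual adds independent (not pair-shared) logit noise of sd 0.65.
  The calibration of that value is a genuine design point, discussed
  below.
* **Planted signals**: 100 DMSs (beta shift −0.5) and 20 DMRs (5
  consecutive CpGs, −0.4 each) are applied to the affected twin with
  clipping to [0, 1]. Defaults plant hypomethylation at constitutively
  methylated sites: that is the compartment where the CV gate admits
  calls at all — a low-methylation baseline has a CV near or above the
  0.25 gate from sampling alone — so it is where the within-pair rule is
  designed to operate.

**Planted truth lives in the analyzable universe.** Planted features are
placed only at sites covered at ≥ 20 reads in every sample and outside
VMR and blacklist intervals, and the stranded counts at planted sites
are drawn conditional on passing the strand-concordance rule. Without
this, a planted DMS would be silently destroyed ~25–30% of the time by
the strand filter alone (the affected twin sits at intermediate
methylation, where per-strand sampling noise at ~15 reads per strand
trips the 20% rule), and recovery metrics would measure the sequencing
lottery rather than the calling rules. The conditioning changes only
which random counts are drawn at the ~200 planted sites; background
sites are untouched.

**Evaluation conventions.** `score_dms_calls()` excludes positions in
planted VMR blocks from DMS scoring — a VMR site carries genuine large
within-pair differences by construction, so a call there is neither a
recovery of planted signal nor a noise artifact. Calls at planted DMR
sites count as true positives (the planted per-site difference of 0.4
exceeds the DMS threshold). Sensitivity is measured over planted DMS
sites present in the analyzed set; the false-discovery proportion over
all scored calls. Similarly, a planted DMR is *testable* when at least 3
of its member CpGs survive QC, and *recovered* when a called region of
the same pair overlaps it with ≥ 3 members. The "no-feature null" used
for specificity plants nothing at all — no DMS, no DMRs and no VMR
blocks — because a VMR block genuinely satisfies the four regional rules
now and then; it is a planted feature, not a false positive.

**Calibrating the VMR noise (sd 0.65).** The qualitative target is the
classic twin-methylome pattern: masking VMRs *raises* co-twin
correlation and *lowers* unrelated correlation. A variance decomposition
shows when that can happen. Writing S for the across-site spread of VMR
baselines, E for the individual-specific VMR variance, B and N for the
background's baseline spread and per-individual noise, and P for the
pair-shared variance: removing the VMR stratum lowers unrelated
correlation only if the VMR stratum's correlation ratio `S/(S+E+N)`
exceeds the background's unrelated ratio `B/(B+P+N)`, and raises co-twin
correlation only if it falls below the background's co-twin ratio. The
VMR stratum must therefore sit strictly *between* the unrelated and
co-twin signal-to-noise regimes — a window whose width is the
twin-unrelated correlation gap itself. Two consequences drive the
defaults: VMR baselines must span both methylation states (making S at
least as large as B; drawn 50/50 here), and the individual VMR noise
must be moderate. sd 0.65 places the stratum mid-window for the default
cohort after all QC filters (the strand filter trims the most deviant
VMR observations, which shifts the window relative to the unfiltered
model — the calibration is to the pipeline's own retained set). Much
larger VMR noise makes masking raise *both* correlations; much smaller
makes it lower both. Real VMRs are more variable than this; the
limitation section returns to that point.

## Problem sizes and determinism

The validation suite runs the rule-equivalence checks on 100 random
instances each (cohorts of ≤ 50 sites for DMS; ≤ 200 sites for region
merging, against exhaustive enumeration), and the recovery and
twin-structure checks on ten replicate cohorts at the full default size
(50,000 sites × 12 samples) plus ten feature-free nulls. A single cohort
of that size simulates and analyses in ~10 s. All randomness flows from
one integer seed per cohort; a fixed seed reproduces every output file
byte for byte.

## What passing these checks does and does not show

The generator reproduces the *structure* that the analysis rules exploit
— bimodal beta landscape, pair-shared methylome similarity, high
inter-individual variance at VMRs, overdispersed depths, strand-split
counts, spike-in conversion — with effect sizes chosen to be
recoverable at 30x depth. It does not model sequence context, CpG
density waves, SNP-induced artifacts, cell-composition heterogeneity of
saliva, batch structure, or array-platform error; correlations in the
synthetic cohorts are correspondingly higher (co-twin ~0.992 vs
unrelated ~0.988) than the values reported for real twin methylomes,
though their ordering and the masking responses match. Recovery rates
measured here are therefore upper bounds for real data, where planted
truth is unknowable and the filters interact with biology rather than
with a known generative model.

## A worked example

```{r example, fig.width = 6, fig.height = 4}
cfg <- sim_config(n_sites = 4000, n_dms = 20, n_dmr = 4,
                  lambda_sites = 1000)
res <- run_twin_pipeline(cfg, seed = 42)
res
glance(res) |> as.data.frame()
head(tidy(res$dms), 3)
autoplot(res)
```
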