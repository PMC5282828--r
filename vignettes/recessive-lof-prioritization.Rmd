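---
title: "Recessive LoF discovery and functional prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recessive LoF discovery and functional prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofprio)
```

# The problem

Parkinson's disease with a young onset is often recessive, but in
cohorts of unrelated cases segregation analysis is impossible and the
implicated alleles are so rare that most genes are supported by a
single carrier. `lofprio` implements the two-arm strategy this
situation calls for: a stringent recessive loss-of-function (LoF)
filter cascade over an annotated case/control exome cohort, and a
battery of downstream statistics — gene-level burden tests, cell-based
RNAi screen effect sizes, organism modifier-screen scores, and
cross-cohort arithmetic — whose outputs are integrated into a single
prioritized gene set.

Because individual-level cohort data cannot be redistributed, every
input is either a verbatim encoding of a published summary table (with
synthetic carrier genotypes) or the output of a seeded synthetic-data
generator with a known truth table. What the package demonstrates is
therefore the *method*: that the cascade, tests, and integration rules
recover planted truth exactly, reproduce all published derived
quantities, and are calibrated where calibration is checkable.

# The filter cascade

A variant is LoF under three rules:

* **Stop-affecting SNVs.** The annotator's `stopgain`/`stoploss`
  classes are accepted as-is; re-deriving SNV consequences is out of
  scope.
* **Frameshift indels** count only when they create an *immediate*
  stop: the codon containing the first edited base must become
  TAA/TAG/TGA in the shifted frame. This is the strictest reading of
  "immediate stop at the position of the indel"; a stop appearing
  k codons downstream does not qualify. The rule is recomputed from
  the coding sequence when a transcript model is supplied, and
  otherwise taken from an `immediate_stop` annotation column, so
  fixtures can carry annotator-verified calls without shipping
  transcript sequences.
* **Splice variants** qualify when they lie in the intron within 2 bp
  of an exon boundary (donor +1/+2, acceptor −1/−2, 1-based inclusive
  exon ends — matching HGVS notation like c.190−2) *and* the adjacent
  exon codes for amino acids. Whether an insertion at the −2 position
  must also disrupt the AG dinucleotide is not specified by the
  distance rule; we implement the distance rule alone.

Rarity is decided against three public sources (ESP6500 European
American, 1000 Genomes European, ExAC non-Finnish European): a variant
passes at the default 1% threshold only if *every source that reports
it* is below threshold. Absence from all sources is treated as
evidence of rarity (the variant passes, flagged novel) and is encoded
as an explicit missing value, never as frequency zero — the
distinction matters downstream.

Homozygous candidates need at least one case homozygote and must
survive an internal-control comparison: excluded when the control
allele frequency exceeds 1% or exceeds the case frequency (ties pass;
frequencies are alternate alleles over called alleles). A variant that
fails this rule but is absent from every public database is *retained
with an exception flag* and a warning, because for such variants the
in-house controls are the only available frequency reference; this is
exactly the situation of the recurrent splice allele in the published
table, and silently dropping it would discard the study's most
interesting recurrent genotype.

Compound-heterozygote candidates require two heterozygous variants on
the same transcript in one case, at least one of them LoF, the partner
either LoF or a deleterious missense allele (no dbSNP identifier and
CADD > 20; the rsid field is the proxy for dbSNP membership since the
annotation build is not re-queried). Pairs closer than 200 bp may sit
on a single sequencing read; the study resolved those by manual read
inspection, which an automated pipeline cannot reproduce, so we
substitute an explicit phase annotation input: within the window,
unknown phase yields a `needs_review` candidate excluded from the
confirmed set, and phase is never guessed. Distant pairs with unknown
phase are kept as `putative`; cis pairs are never candidates.

Every candidate carries a filter trail naming each rule it passed,
failed, or was excepted from, and `run_cascade()` reports per-stage
variant counts as an audit trail. Two reporting decisions follow the
study's practice: upstream QC (the variant-caller's quality filters)
enters only as an optional boolean pre-filter column, and genes
already known from prescreening are reported, not removed.

# Burden testing

The rare/common boundary is `1/sqrt(2n)` at the post-QC sample count,
reported to two significant figures (0.018 at n = 1540; 0.0063 at
n = 12771). Two variant classes are tested: *deleterious* (LoF plus
missense with CADD > 20) and *missense* (all amino-acid-changing
variants plus LoF).

The one-sided burden statistic collapses qualifying counts per sample
and scores them against covariate-adjusted phenotype residuals
(intercept plus any supplied covariates, via QR projection); the
variance-component statistic is the quadratic form
`Q = r' G W G' r` with `W = diag(dbeta(maf, 1, 25)^2)` — the
squared-density convention of the variance-component literature,
switchable to uniform. The published analysis used a combined
common-plus-rare test whose exact mixing is not stated; we implement
the combination as `0.5 Q_rare + 0.5 Q_common` (each component scaled
by its variant count so neither side dominates by dimension), declare
the weight in the design object, and document it as an assumption.

All inference is by permutation of affection status with covariates
held to samples: `p = (1 + #{perm >= obs}) / (1 + B)`, ties counted
conservatively, B = 10000 by default. No analytic
mixture-of-chi-square null is used — permutation is the inferential
anchor, which also makes p-values invariant to monotone transforms of
the statistic. Common-variant pruning is a greedy r²-window pruner
(window 50, step 5, r² ceiling 1/3 ≈ a pairwise variance-inflation
factor of 1.5) over a supplied LD matrix.

"10× coverage" as a covariate is ambiguous in the source; we treat it
as a per-sample mean-coverage column, i.e. just another numeric
covariate.

# Screen statistics

Per-well summaries are medians over QC-passing cells (interphase,
in-focus, well-segmented, non-border); wells with fewer than 50
passing cells are invalid — the floor for "strongly decreased cell
number" is unstated in the source, so 50 is a package default and a
config knob. Translocation wells score cells positive at strictly
more than two spots and report the positive:negative ratio, with a
0.5 continuity offset (flagged) when there are no negatives.
Normalization divides each well by the *median of negative-control
well medians on its plate* (median-of-medians rather than a pooled
median; also unstated, chosen for robustness to unequal control cell
counts).

The effect size is the robust SSMD:
`(median_t − median_c) / (1.4826 sqrt(MAD_t² + MAD_c²))` with the raw
median absolute deviation. The source prints only the statistic's
name and the ±4 cutoff; the median/MAD form with the normal
consistency constant follows the robust-SSMD literature the cutoff
comes from. A clone is significant iff |SSMD| > 4 (strict) *and* its
Benjamini–Hochberg-adjusted Mann–Whitney p-value clears the FDR level
— the source lists both criteria without stating their conjunction,
so the conjunction is the default and `ssmd_only` is available. A
gene needs two significant independent clones; significant clones
sharing an identical 7-mer seed (guide positions 2–8) are flagged
seed-confounded rather than dropped. The FDR method is fixed to
Benjamini–Hochberg (the field default; the source says only "FDR").
Assay quality is the robust Z' factor,
`1 − 3(1.4826 MAD_pos + 1.4826 MAD_neg)/|median_pos − median_neg|`.

# Organism screens

Fly enhancer calls: penetrance is abnormal retinae over examined
retinae (at least eight per line, else flagged under-sampled;
blinded-triplicate scorer disagreement resolves by per-retina
majority, then a single penetrance is computed — the order is
unstated in the source). A gene is an enhancer iff **two**
independent lines each reach penetrance **≥ 0.5**. Note the deliberate
asymmetry: the penetrance threshold is inclusive ("50% or greater")
while the SSMD cutoff is strict ("greater than 4"), both following
the stated wording exactly. Vacuole quantification sums vacuoles with
diameter *strictly* greater than 4 μm over total retinal area, three
animals per genotype, compared by unpaired two-tailed t-test. Worm
viability uses a one-sided t-test in the reduction direction;
relative body bends normalize the treatment mean to the control mean
with a delta-method standard error.

# Evidence integration and cross-cohort arithmetic

Fold enrichment is a ratio of carrier frequencies; the tolerability
verdict compares a reference-population homozygote frequency to the
young-onset disease prevalence (default 0.041%), with equality
resolving to `cannot_exclude` (a frequency *at* the prevalence cannot
rule the gene out). Replication matching is exact on
(chrom, pos, ref, alt) plus a qualifying recessive genotype in the
replication cohort; the shared-heterozygote scan requires two or more
index cases, no control carriers, and public frequencies below 0.1%.
GWAS lookups take suggestive signals (p < 1e-4) within 1 Mb of the
gene, grouped into peaks at a 250 kb merge distance (a package choice
standing in for visual locus grouping). Pairwise relatedness is the
standard GRM entry over SNPs with MAF ≥ 0.01.

The prioritization rule — a gene needs at least one functional flag
(morphology, translocation, or synuclein-enhancer) *and* at least one
genetic-replication flag — is inferred from the published five-gene
intersection and verified against the encoded table; any-flag
suffices on each side because that reproduces the printed set, and
the rule is overridable. Annotation concordance between transcript
databases is modelled as a boolean input flag, not recomputed.

# The synthetic-data generators

`generate_cohort()` draws background genotypes under Hardy–Weinberg
equilibrium from a frequency spectrum of 70% singleton-scale alleles
(1/2N at the reference-panel size), 25% rare tail (scaled Beta below
1%), and 5% common — not an empirical site-frequency spectrum, but
chosen once so that every MAF rule in the cascade is exercised.
Planted genes receive their recessive genotypes in randomly chosen
cases; compound-het plants are explicitly trans-phased so the
confirmed (not `needs_review`) path is exercised. The standard decoy
set contains one gene per cascade rule (common public frequency,
non-LoF class, control-common internal frequency, low-CADD partner,
split transcripts, control-only homozygote), each violating exactly
that rule, so rejection can be attributed. With zero annotation
noise, planted-gene recall and decoy rejection are exact, and the
tests assert this.

`generate_plates()` emits per-*well* normalized medians — the level
at which SSMD and hit calling operate — rather than per-cell tables;
per-cell QC and translocation counting are tested on small in-code
cell tables instead. Each plate carries its own controls and a
log-normal multiplicative offset that normalization must remove.
Effects are planted in SSMD units: with well noise sd σ, a planted
effect e shifts the clone mean by `e·σ·√2`, the asymptotic SSMD
denominator for normal noise. At six replicates the median/MAD
estimator is noisy and right-skewed (simulation medians sit near the
planted value; means run ~20% high), which is why hit calling uses a
threshold far from the null rather than the point estimate.

`discovery_table_fixture()` encodes the published discovery table verbatim —
coordinates, alleles, dbSNP ids, effect classes, ExAC European
frequencies, CADD scores, transcripts, modes, and validation flags —
and attaches a deterministic synthetic carrier structure: one case
homozygote per homozygous gene, one trans-phased compound-het case
per compound-het gene, and for the recurrent splice gene four case
homozygotes plus one control homozygote with heterozygote counts
matching the printed case/control frequencies (0.073/0.052). The
genotypes are synthetic; no individual-level data are redistributed.

# What the tests do and do not show

Passing tests show that the implementation follows its stated rules
exactly, recovers planted truth on clean synthetic data, is calibrated
under a null (permutation type-I error within binomial bounds of 0.05
on 200 genes × 1000 permutations), and reproduces every published
*derived* quantity: the 27/18/9 candidate counts, the 40-fold
enrichment, the 0.028% tolerability frequency, the 0.018/0.0063
cutoffs, and the 15/13/6/4/7/5 evidence counts. They cannot show
performance on real exomes: real annotation error, capture
heterogeneity, population structure, and the screen's biological
variability are all absent from the generators. Quantities that
depend on restricted raw data — the screen's observed Z' of 0.61 and
the real per-gene burden p-values — are out of reach at desk scale
and are covered instead by the oracle and calibration tests.

Problem sizes in the shipped tests and drivers (cohorts of a few
hundred samples, 200-gene null panels, 1000 permutations, 300-seed
Monte-Carlo checks) are the package's chosen defaults for a
reproducible desk-scale demonstration; all scale linearly if raised.

# Numerical and degenerate-input conventions

* Both MADs zero in SSMD: 0 when medians agree, signed infinity
  otherwise; coincident control medians make Z' undefined (`NA`).
* A burden gene with no qualifying variant is `untestable` (distinct
  from a statistic of 0, which all-zero genotype columns produce).
* Permutation p-values count ties as exceedances and never fall below
  `1/(B+1)`.
* Zero translocation negatives trigger a flagged continuity offset.
* Multi-allelic variant rows are rejected at ingest; all rules are
  per-allele, so sites must be pre-split.
* Coordinates are 1-based inclusive everywhere; insertions are
  expected left-aligned as in standard VCF normalization.
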