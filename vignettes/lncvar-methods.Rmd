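---
title: "Models and methods behind lncvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lncvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncvar)
```

# The problem

Long non-coding RNAs (lncRNAs) are harder to annotate than mRNAs: they
are expressed at lower levels, more tissue-specifically, are less
enriched by polyA selection, are spliced less efficiently — and, the
motivating observation for this package, their expression varies more
between healthy individuals than mRNA expression does. A transcript
that is well expressed in one donor and silent in another has a low
chance of entering a reference annotation built from few donors.

`lncvar` implements the analysis machinery needed to quantify these
effects in multi-donor bulk RNA-seq: a filter cascade that turns an
assembled transcriptome into an mRNA and a lncRNA annotation, positional
and public-annotation (PA) coverage classifiers, RPKM-based expression
summaries, a per-splice-site splicing-efficiency score, the
inter-/intra-individual variability statistics, and a donor-saturation
("discovery curve") analysis. A synthetic-data generator with planted
ground truth makes every stage testable offline.

# The identification cascade

Candidate transcript models (e.g. a Cufflinks/Cuffmerge assembly read
from BED12) pass four ordered stages:

1. **Structure** — keep multi-exonic transcripts with exonic length
   strictly greater than 200 bp (`filter_structure`).
2. **Coding overlap** — a candidate sharing at least 1 bp of same-strand
   exonic overlap with a protein-coding reference exon becomes an mRNA;
   otherwise same-strand exonic overlap with a pseudogene exon discards
   it (`partition_by_coding_overlap`). Precedence is mRNA over
   pseudogene; the source material does not state an order, and keeping
   coding-supported models is the conservative choice.
3. **Coding potential** — a lncRNA candidate is kept iff its RNAcode
   score is below 18 *and* its CPC score below 1.6
   (`coding_potential_filter`). Both cutoffs are strict, matching the
   "score < threshold" reading of the published criteria. A transcript
   for which the scoring tools emitted nothing is kept and flagged
   (RNAcode produces no score when an alignment shows no coding signal,
   so absence is evidence of absence here); `missing_score_policy =
   "drop"` switches to the conservative behaviour.
4. **Sense overlap** — lncRNAs whose *span* overlaps a protein-coding
   gene span on the same strand are removed (`remove_sense_overlap`).
   Span (not exon) overlap is deliberate: intronic sense lncRNAs are the
   canonical confounder of locus-level expression estimates and must go,
   and they have no exonic overlap with their host.

Each stage reports input/kept/removed counts that telescope exactly,
and `run_lnc_filter_cascade` composes the stages and groups survivors
into loci.

## Loci

A locus is a connected component of the graph whose edges join
same-chromosome, same-strand transcripts with at least 1 bp of *exonic*
overlap (transitive closure). Upstream assemblers do not document their
grouping rule; exonic (rather than span) overlap keeps the antisense
partner of a gene in its own locus and does not fuse genes that merely
share an intron. Unstranded records only group with other unstranded
records and are flagged — strand must be resolved upstream. Locus
identifiers are assigned in (chromosome, start) order, so locus naming
is deterministic.

# Classifiers

**Positional classes** (precedence bidirectional > antisense >
intergenic; each lncRNA gets exactly one label):

* *bidirectional* — the transcript TSS lies within ±1.5 kb of a
  protein-coding TSS (the promoter window). A locus is bidirectional if
  **any** member TSS qualifies.
* *antisense* — the span overlaps a protein-coding gene span on the
  opposite strand.
* *intergenic* — no overlap with any protein-coding gene.

Precedence is forced by the fact that the three published percentages
sum to 100 %; promoter sharing is the most specific signal, so it wins.

**PA coverage classes.** Against a merged public lncRNA annotation, an
exon is *covered* when it has ≥ 1 bp same-strand overlap with any PA
exon. A transcript is `in_PA` when all exons are covered,
`isoform_not_in_PA` when some but not all are, `not_in_PA` when none
are. Whether "full exonic overlap" should demand exact splice junctions
is genuinely open; the default is per-exon ≥ 1 bp overlap, and
`strict_junctions = TRUE` switches to exact exon coordinates. A locus
is *new* only if every member is `not_in_PA`.

# Expression

All expression is RPKM: `count * 1e9 / (length_bp * total_mapped_reads)`,
with exonic length at the transcript level and intron-inclusive span
length at the locus level. The detection cutoff is RPKM 0.2 throughout.
Donor-level expression is the arithmetic mean of a donor's replicates,
always within a single library protocol. Expression bins are left-open:
(0.5,1], (1,2], (2,4], (4,8], (8,∞), keyed on the *maximum* donor mean;
features with a maximum at or below 0.5 fall outside all bins and are
reported as bin 0 ("unbinned") rather than silently dropped.

PolyA+ enrichment is mean(polyA RPKM)/mean(ribo-depleted RPKM) per
feature, with features undetected in the ribo-depleted data (mean <
0.2) excluded. Tissue specificity uses an inclusive three-fold rule —
specific iff focal expression ≥ 3 × the panel maximum; when the panel
maximum is zero the ratio is undefined and the feature is called
specific iff detected, and flagged.

# Splicing efficiency

For every exon/intron junction, two windows of up to 45 bp are placed —
one exonic, one intronic — leaving out 5 bp on each side of the
junction (splice-site placement in assemblies is imprecise). In each
donor,

$$S = 100 \left(1 - \frac{\mathrm{RPKM}_{intronic}}{\mathrm{RPKM}_{exonic}}\right),$$

clamped to [0, 100]: no intronic signal gives 100, intronic signal at or
above exonic gives 0 (full absence of splicing). A site is discarded
outright when its exonic RPKM falls below 0.2 in *any* donor. Per-site
values are averaged over donors; a transcript's efficiency is that of
its best (maximal) valid site, and a locus takes the maximum over its
transcripts. Both ends of every intron are scored as separate sites.

Numerical edges the source material does not address: windows truncate
when the flanking exon (available length `exon − 5`) or intron
(`intron − 10`, an excluded zone at each end) is short, and a site is
skipped when either truncated window would be under 10 bp — a ratio of
two sub-10-bp RPKMs is noise.

# Variability statistics

* **CV (normalized SD)** — sample standard deviation (n−1 denominator,
  matching R's `sd`) of the donor means divided by their mean.
  Undefined at mean zero; such features are excluded.
* **ANOVA** — one-way fixed-effects ANOVA with donor as the factor and
  the replicates as within-group observations, computed in closed form
  over all features at once (group sums of squares + `pf`), verified
  against `aov` in the tests. Degenerate rows: all-equal values give
  p = 1 (flagged, never significant); zero within-group variance with
  real between-group spread gives p = 0.
* **BH FDR** — standard step-up with running-minimum monotonicity.
* **Fold change** — max(donor mean) / max(min(donor mean), 0.2). The
  floor at the detection cutoff prevents near-zero denominators from
  manufacturing huge fold changes; the published criteria do not state
  their handling of undetected minima.
* **Significance** — p < 0.01 ∧ q < 0.05 ∧ FC > 3 ∧ detected in ≥ 1
  donor. Chromosomes X and Y are excluded from all variability
  analyses, as are features undetected in every donor.
* **Equalized Mann–Whitney** — the larger population is subsampled to
  the smaller's size, a two-sided tie-corrected test is run, and the
  procedure repeats three times with sub-seeds derived
  deterministically from the master seed; the three p-values are
  averaged. This is how unequal population sizes (e.g. ~2,000 lncRNAs
  vs ~120,000 mRNAs in real data) are prevented from inflating
  significance.
* **Reproducibility** — intra-individual: in every donor the replicates
  agree on detection (all > 0.2 or all ≤ 0.2); inter-individual: donor
  mean > 0.2 in all donors. The inter definition counts only the
  all-detected branch; all-undetected features are reported separately
  rather than folded into "reproducible".

# Donor saturation

Real discovery curves re-assemble reads per donor pool; that is out of
scope here (and in the acceptance setting, impossible). Instead,
assembly is **emulated by a detection model**: a transcript is found in
a pool of four donors when the pooled (mean) expression reaches a
threshold θ = 0.2, the detection cutoff — optionally softened to a
logistic probability that is exactly 0.5 at θ. Pools are 2 female + 2
male donors from one population; k ∈ {1,…,30} assemblies are merged
(de-duplicating by exact intron-chain identity, a 0-tolerance stand-in
for Cuffmerge's matching), pushed through the same identification
cascade, and loci are counted; each k is repeated three times (once at
k = 30).

# The synthetic world

The generator states a world and the tests measure whether the
pipeline recovers it; its defaults are the published class-level values:

| parameter | mRNA | lncRNA |
|---|---|---|
| median RPKM | 6.14 | 0.65 |
| inter-donor CV target | 0.15 | 0.29 |
| median splicing efficiency | 99.02 | 88.13 |
| median polyA+ enrichment | 2.62 | 1.56 |
| transcripts per locus (mean) | 13.2 | 3.9 |
| tissue-specific fraction | 4 % | 32.5 % |
| positional mix (bid/anti/inter) | — | 25/33/42 % |
| PA mix (in/isoform/not) | — | 32/37/31 % |

Expression is a lognormal hierarchy
`x_tij = b_t · d_ti · e_tij` (baseline × donor effect × replicate
noise); the inter-donor log-SD comes from the CV identity
σ = √(ln(1+CV²)) — 0.149 for mRNA, 0.284 for lncRNA — so the CV target
is analytic, not fitted. Replicate noise defaults to log-SD 0.1,
consistent with the high intra-individual reproducibility the package
is meant to reproduce; the baseline log-SD of 1.5 spreads transcripts
over the 0.2–1000 RPKM range seen in practice. The polyA matrix is the
ribo-depleted matrix times a per-transcript lognormal enrichment
factor; the class medians are anchored on the ribo-depleted matrix, so
recovery checks compare against planted values, not the published
absolute medians (which are PolyA+ measurements).

Geometry is planted unambiguously: bidirectional lncRNAs start 0.3–1.2
kb from a coding partner's TSS on the opposite strand without body
overlap, antisense lncRNAs nest in the giant intron of an
opposite-strand host with TSSs ≥ 8 kb apart, intergenic loci are ≥ 30
kb from anything, and every isoform of a locus carries the locus
scaffold plus one unique extra exon, giving distinct intron chains but
guaranteed exonic overlap. Known loci contribute their `in_PA` members
verbatim to the PA set; new loci contribute nothing. Because the
geometry is forced, classifier tests can demand 100 % label recovery —
a green test establishes the classifier implements the rules, *not*
that the rules are unambiguous on messy real annotations.

Splicing truth: each transcript draws an intronic fraction `f` from a
lognormal whose median is `1 − S_median/100`; its designated best site
uses `f` and the remaining sites 2–5 × worse, so the max-over-sites
estimator targets a known value. Window counts are Poisson with mean
proportional to donor-pooled expression and an *effective* window
length of window + read length — short windows are hit by every read
overlapping them, which is also why the window RPKMs the efficiency
module computes are inflated ~3× relative to transcript RPKM, exactly
as overlap-counting tools behave on 45 bp features; the intronic/exonic
ratio, and hence S, is unaffected.

For the saturation world, continuous lognormal donor variability alone
produces only ~1.5× locus growth from 4 to 120 donors. The discovery
effect in real data is driven by transcripts that are *off* in many
donors (the motivating example is a lncRNA detected in 93 of 462
donors), so lncRNA loci additionally draw a per-locus donor
on-probability π ~ Beta(0.08, 4) (mRNAs are always on), and donor
effects use lymphoblastoid-scale CVs (0.56 lncRNA / 0.24 mRNA). The
Beta parameters were calibrated once so the emulated curve reproduces
the published ~3× lncRNA growth with a flat mRNA curve, and frozen;
with them, 4 donors find ≈ 31 % of the 120-donor lncRNA loci
(published: ≈ 33 %). The world is scaled to 600 lncRNA + 800 mRNA loci
so the full 12-point curve runs in minutes; the acceptance quantities
are ratios, which do not depend on the absolute scale.

## What the generator does *not* emulate

Read-level effects (mappability, positional coverage bias, library
prep), correlated donor effects across transcripts (real donors shift
globally; here donor effects are independent per feature), mixture
structure within a class (every synthetic lncRNA has the same CV
target, so the synthetic "% significantly variable" — about 7.5 % vs
0 % at defaults — is far from the published 23.9 %/4.2 %, even though
the ordering the acceptance criterion checks is robust), annotation
errors in the PA set, and sequence content of any kind.

# Reproducibility and numerical choices

One master seed drives everything; stage seeds and the equalized-MWU
sub-seeds derive from it deterministically (`derive_seeds`), and all
derived seeds stay below 2³¹. Generation is byte-identical across runs
with the same seed. Ties in the Mann–Whitney test use the normal
approximation with continuity and tie correction. BH caps q at 1. The
fold-change floor, the p = 1 convention for zero-variance features, and
the bin-0 bucket are the three places a silent NA could otherwise leak
into downstream counts.

# Known limitations

* The cascade assumes the coding-potential scores cleanly separate
  classes; real RNAcode/CPC output is noisy, and the synthetic world
  plants perfectly separable scores.
* The detection-model emulation of assembly ignores assembler-specific
  sensitivity to coverage shape, so absolute saturation counts are not
  comparable to read-level results — only curve shapes are.
* Locus-level RPKM (intron-inclusive span) is accepted as input but the
  generator only emits transcript-level matrices.
* No TPM or count-model normalization: the statistic of record is RPKM
  because every published threshold (0.2, 1, the bins) is an RPKM.
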