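---
title: "Methods: error-based modification calling, threshold calibration, and differential analysis"
author: "modcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: error-based modification calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modcal)
```

## The detection model

Direct RNA sequencing reads native strands, so base modifications are
present during basecalling and perturb it. Error-based callers exploit
this: at every transcript position they compare the error of specific
bases (ESB) in the native sample with the ESB in an unmodified IVT control
of the same transcriptome, summarizing the evidence as ESB test, ESB
control, an odds ratio (OddR) and an adjusted p-value. Internally modcal
keeps ESB as a fraction in [0, 1]; input dialects declare their scale and
`readSiteTable()` converts on read, which avoids silent 100-fold errors
(the literature mixes "%ESB" with fractional values).

A position is called modified when all four cutoffs hold simultaneously,
with inclusive comparisons matching how such thresholds are conventionally
printed:

* ESB test ≥ `esbTestMin` — enough error signal in the native sample;
* ESB control ≤ `esbControlMax` — the position is quiet in the IVT
  control, excluding systemic sequencing error;
* OddR ≥ `oddrMin` — the native error is disproportionate;
* adjusted p ≤ `padjMax`.

Two signal properties shape everything downstream. First, a modification
elevates error up to about 10 nt on either side of its true position (the
"smear"), so single-nucleotide precision claims are not meaningful;
adjacent called positions are merged into **signal regions**
(`mergeRegions()`), each treated as one signal harbouring one or more
modifications. Second, reliable calling needs read depth; 20 reads per
molecule is the conventional floor, below which a molecule is treated as
insufficiently covered.

## Calibration against the known-site catalogue

Bacterial tRNA/rRNA modification sites are catalogued (MODOMICS symbols),
which turns cutoff choice into a supervised problem. `precisionRecall()`
defines:

* **recall** — the fraction of catalogued sites with a called position at
  the exact site. A configuration switch (`recallTolerance`) widens this,
  but the default is exact matching: offset hits are tracked separately as
  their own detection category rather than silently credited.
* **precision** — region-tolerant: a signal region is true if it contains
  a known site or lies within ±`tolerance` (default 10) nt of one. This
  credits smear-shifted signal to its causal modification while still
  penalizing isolated spurious regions.

`gridSearch()` evaluates every combination of a `GridSpec` and selects the
one maximizing recall subject to precision ≥ 85%. The default grid is
20 × 20 × 20 × 4 = 32,000 combinations; the per-parameter lists are a
design choice (the combination count is conventional, its composition is
not) built so that the conventional cutoff set — ESB test 0.1, ESB control
0.01 (i.e. 1%), OddR 3, adjusted p .05 — is a grid member. Where several
values of one parameter give identical precision and recall, the least
restrictive is selected: the relaxation starts from the most restrictive
argmax-recall combination and relaxes one parameter at a time in the fixed
order adjusted p, ESB control, OddR, ESB test, accepting a relaxation only
if it leaves both precision and recall unchanged. Not-detectable
modification types are, by default, excluded from neither the precision
matching nor the recall denominator (`detectableOnly = FALSE`); flipping
the switch answers the "how much could error-based calling ever see"
question instead.

Five-way benchmarking (`classifyKnownSites()`) assigns each catalogued
site one category by precedence: `type_not_detectable` (some chemistries —
m5C, s4U, s2C, mnm5U, lysidine, m6t6A, i6A, m4Cm — do not perturb
basecalling enough to register), then `depth_insufficient`, then
`detected`, then `detected_with_offset` (nearest call within ±10 nt; ties
go to the upstream position), else `not_detected`. The precedence mirrors
the convention of reporting type-undetectability before coverage, so the
categories partition the catalogue deterministically.

### Rounding of reported percentages

Percentages are rounded half-up to one decimal (`roundHalfUp()`), not with
R's banker's rounding. Published tables are not always consistent —
e.g. 31/32 = 96.875% is sometimes printed as 96.8 (truncation) while
56/387 = 14.4702% is printed as 14.5 (rounding) — so summaries also carry
the raw fraction and a truncated-to-one-decimal column
(`truncateDecimal()`), making either printing convention auditable.

## Regions, biotypes and metagene positions

`annotateRegions()` assigns each region the biotype of its midpoint with
the fixed precedence tRNA > rRNA > CDS > 5'UTR > 3'UTR > ncRNA >
intergenic. The midpoint rule is a design choice: how regions straddling a
boundary should be attributed is genuinely open, and the midpoint is the
least surprising deterministic resolution. tmRNA and pseudogene features
count as noncoding RNA. `biotypeProportions()` reports counts and
percentages over a configurable biotype set, excluding tRNA and rRNA by
default (novel-site reporting conventionally excludes the heavily modified
stable RNAs); it counts regions, not constituent sites — pass width-1
regions for site-level counting.

`metagenePositions()` places each mRNA region on a normalized [0, 3)
scale: 5'UTR → [0, 1), CDS → [1, 2), 3'UTR → [2, 3), position within a
segment being the midpoint's offset from the segment's 5' end divided by
segment length. Minus-strand segments are traversed 3'←5' so 0 is always
the transcript 5' end. The unit-band scale is a design choice ("normalized
relative location" admits several conventions); it keeps segments equally
wide regardless of their nucleotide lengths.

## Differential analysis between conditions

`computeDeltaEsb()` computes ΔESB = ESB test − ESB control per condition
for every position called in either condition, setting ΔESB to 0 in a
condition where the position is not detected. The zeroing makes the
operation total (every union position yields a record) at the cost of
creating undefined between-condition ratios where ΔESB(a) = 0; such
records carry `ratio = NA` and are excluded from the MS correlation rather
than propagating infinities. Change labels use an `eps = 1e-6` unchanged
band on the fraction scale — "unchanged" is otherwise undefined for
continuous data, and 1e-6 is far below any biologically meaningful ESB
difference.

`compareConditions()` labels the union of called positions as `shared`,
`unique_modification` (called once, molecule covered in both conditions)
or `modification_in_unique_rna` (molecule below the 20-read floor in
exactly one condition — the transcript, not the modification, is
condition-specific).

`msCorrelation()` cross-validates sequencing against mass spectrometry:
per modification type, the sequencing ratio mean ΔESB(b) / mean ΔESB(a)
is paired with the MS abundance ratio, and the pairs are compared by
Pearson correlation. Ratio-vs-ratio pairing (rather than correlating raw
ΔESB with raw abundances) is the default because the two instruments'
absolute scales are incommensurable; relative change is the shared
quantity. For this stoichiometry-style analysis, "detected" means present
in the dataset at sufficient depth (`detectedSites()`), not passing the
strict four-parameter cutoffs — stoichiometry comparison at catalogued
sites should not inherit calling stringency, and threshold-boundary
flicker between conditions would otherwise zero one side of many sites.

## SELECT ΔΔCT classification

SELECT interrogates one base by single-base elongation plus nick ligation;
m6A at the interrogated base hinders both. Per assay and sample type,
`selectClassify()` averages ΔCT = CT(target) − CT(A-control) over
replicates (arithmetic mean of CT before differencing — replicate pairing
is not assumed — with the replicate SD reported), then
ΔΔCT = ΔCT(WT) − ΔCT(reference), where the reference is IVT RNA or a
methyltransferase-mutant RNA. An assay classifies as modified iff
ΔΔCT ≤ −1, the threshold itself included. The sign convention is fixed
empirically by the published worked values (modified sites at −1.03 and
−2.5): a modified target depresses ΔCT in the WT relative to the
reference, and the generator emulates exactly that displacement.

## The synthetic generator

`simulateExperiment()` produces every input the pipeline consumes, with a
recorded ground truth. What it emulates, and the defaults:

* **Annotation** — 80 molecules (30 tRNA at 76 nt, 2 rRNA at 1542/2904
  nt, 40 mRNAs with 5'UTR/CDS/3'UTR on random strands, 8 ncRNAs), each
  padded by a 10-nt intergenic flank.
* **Background ESB** — Beta(1, 199) (mean 0.5%), independently per
  position and sample, plus a sparse systemic "spike" family (rate 0.004)
  with ESB test uniform in (0.05, 0.095) and a quiet control: the kind of
  reproducible mid-level noise that punishes an over-permissive ESB-test
  cutoff with false regions while staying below the 0.1 cutoff.
* **Planted sites** — ~250 sites with per-biotype type pools (including
  non-detectable types, which emit no signal); stoichiometry uniform in
  (0.3, 0.95); ESB elevation = 0.45 × stoichiometry at the site with a
  geometric smear (factor 0.5/nt, truncated at ±10 nt — the functional
  form of the smear is a design choice; only its extent is established).
* **Depth** — molecule abundance log-normal and *shared between
  conditions* (as transcript abundance is), with a 0.25-log-sd
  condition jitter; biotype-dependent means make rRNA coverage always
  ample, tRNA moderate, and leave ~15% of mRNA/ncRNA molecules below the
  20-read floor.
* **p-values** — a deterministic monotone transform,
  p = 10^(−3 · max(ΔESB, 0) · √min(depth, 400)): sufficient to exercise
  threshold logic without simulating read-level tests, and exactly
  reproducible.
* **Odds ratio** — ESB test over ESB control floored at 1e-3.
* **Assays** — MS abundance per type = mean planted stoichiometry × 3 per
  1000 nucleosides with 5% multiplicative noise; SELECT assays at 6
  planted and 4 unmodified mRNA positions with a −2.5 ΔΔCT displacement
  and 0.05-cycle well noise.

By construction the planted truth is separable at the threshold set
(0.1, 0.01, 3, 0.05): the spike family caps precision below 85% for
ESB-test cutoffs under 0.1, stoichiometries below ~0.43 make a 0.2 cutoff
lose recall, and the recovery grids place the remaining planted values at
their least-restrictive ends so the documented tie-break selects them.

What the generator does **not** emulate: read-level signal (squiggles),
sequence-context-dependent error profiles, correlated errors between
neighbouring positions beyond the deterministic smear, caller-specific
p-value behaviour, partial or biased IVT coverage, and multi-modification
interference within one smear window. Passing recovery tests therefore
demonstrates the correctness of the calibration, merging and differential
logic under the assumed signal structure — not caller performance on real
nanopore data.

## Problem sizes and numerical choices

Test and acceptance runs use the default 80-molecule profile (~31,000
site rows per condition), 3<sup>4</sup>-combination recovery grids, up to
5<sup>4</sup>-combination oracle-equivalence grids, 1,000-instance
brute-force cross-checks for the combinatorial kernels, and a 100-seed
Monte Carlo for the MS correlation — sizes chosen so the whole suite
completes in a few minutes while every module is exercised at realistic
shape. Degenerate inputs are defined, not patched: an empty called set
yields precision NA (flagged) and recall 0; an empty grid is rejected; a
grid with no feasible combination returns the full landscape with a
warning and no best point; zero-length metagene segments are an error.

## Known limitations

* Biotype annotation assumes transcript-level (molecule) coordinates; no
  genome-to-transcript projection or splicing is provided.
* The ELIGOS-style input dialect is a best-effort column mapping; callers
  vary and the `native` dialect is the stable interface.
* `msCorrelation()` requires ≥ 3 paired modification types and drops
  types with nonpositive mean ΔESB in the denominator condition.
* Exact-position recall understates sensitivity when a caller
  systematically reports offset signal; the offset category quantifies
  this but the grid search does not credit it by default.
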