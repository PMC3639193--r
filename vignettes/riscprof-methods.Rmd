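---
title: "Expression-weighted Argonaute footprint profiling with riscprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-weighted Argonaute footprint profiling with riscprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riscprof)
```

## The problem

Differential expression of a microRNA says little about its activity: what
matters is how much of it is engaged in the RNA-induced silencing complex
(RISC), base-paired with an mRNA target. Ago HITS-CLIP captures exactly
that engagement: UV cross-linking followed by Argonaute immunoprecipitation
yields two sequencing libraries per sample — a short library of the miRNAs
resident in the RISC ("Ago-short"), and a library of the mRNA fragments
they were bound to. riscprof analyses such an experiment in a synchronized
time-course design (two biological replicates at four time points: a
quiescent reference `0h` and `1h`, `36h`, `48h` states, as in liver
regeneration after partial hepatectomy, where these correspond to G0, G1, S
and M phases of the hepatocyte cell cycle).

Everything happens in *transcript space*: CLIP mRNA fragments are assumed
to be aligned to an mRNA catalogue, so coordinates are 0-based half-open
positions on the sense strand of a transcript and no genome liftover
exists anywhere in the package.

## The model and its stages

**RISC loading (RPM).** Each miRNA's recruitment is its read count in the
Ago-short library per million aligned miRNA reads of that replicate
library. A miRNA counts as *RISC-loaded* when its replicate-mean RPM
reaches 100 at one or more time points (the threshold is inclusive; the
boundary is unit-tested). Because average RISC occupancy is approximately
stationary over the time course, cross-time comparability is restored by a
global normalization: each library is rescaled so the median log-ratio of
its RPM to the quiescent-mean RPM, over miRNAs at or above 1,000 RPM in
the reference, is zero, and the reference libraries' factors are
geometric-mean-centered at 1. A 0.5 RPM pseudocount guards only the
log-ratios; reported RPM values are never shifted.

**Differential loading.** Fold changes are replicate-mean normalized RPM at
each post-quiescent time point over the quiescent mean; only miRNAs at or
above the stricter 1,000 RPM floor (at either compared time point) are
testable, and calls are made at a Benjamini–Hochberg FDR of at most 20%
within each time point. With two replicates per condition, per-miRNA
variance estimates are hopeless on their own; the default test is limma's
moderated t on log2 normalized RPM, which shrinks variances across miRNAs
and keeps honest tail behaviour. A plain z-test with a single variance
pooled across high-abundance miRNAs is available
(`method = "pooled_z"`); in null simulations its heavier-than-normal log
tails make it anti-conservative at exactly the significance levels BH
uses with hundreds of tests, which is why it is not the default.

**Footprint calling.** The 5' ends ("starts") of CLIP mRNA fragments are
catalogued per transcript, and footprints are coalesced greedily around
the locally strongest accumulations: take the position with the maximal
start count (ties broken 5'-most for determinism), stop when that count
drops below `min_reads = 5`, assign all starts within ±10 nt to the
footprint, zero the consumed window, and repeat. The footprint interval is
`[anchor, anchor + 50)` clipped to the transcript; 50 nt comfortably
contains the 5–43 nt window used downstream for MRE confirmation. The
extent, window and depth floor are conventions of this package (configurable
in `riscprof_config()`); published footprint totals from any particular
experiment depend on such conventions and are not comparable across them.
The greedy caller is validated by exact equivalence with a brute-force
reference on a thousand random start vectors.

**Expression weighting.** RNA-seq abundance is computed as RPKM
(reads / kb / million). A footprint's *strength* is its RPM in the CLIP
mRNA library divided by the transcript's RPKM in the matching (time point,
replicate) — occupancy per unit of available transcript. Transcripts below
an RPKM floor of 0.1 give undefined strengths (flagged, excluded
downstream) rather than exploding ratios. The *total regulatory load*
(TRL) of a transcript is the sum of its footprint strengths, computed per
replicate and then averaged across the two replicates; transcripts with a
TRL strictly over 1 enter the profile matrix (a load of exactly 1 is
excluded — the wording "over 1" is strict and unit-tested).

**Profile matrices and clustering.** Both the mRNA (RPKM, floor: at least
2 RPKM at one time point) and TRL (floor: over 1) matrices are built the
same way: log2(value + 0.1) per replicate library, quantile normalization
across libraries (`limma::normalizeBetweenArrays`), replicate averaging.
The 0.1 pseudocount keeps zero entries finite while preserving order; the
floors are applied to pre-normalization replicate means, requiring at
least one passing time point. Profiles are row-mean-centered (shape, not
level — z-scoring would erase amplitude differences that are biologically
meaningful here) and clustered with `stats::kmeans` over K = 4..30 with a
fixed seed schedule and 25 restarts per K, reporting the K = 12 partition
alongside the full inertia curve. `stats::kmeans` refuses K equal to the
row count; the package returns the exact trivial partition (inertia 0) in
that case. Contrasting a gene's mRNA and TRL profiles reports the lead/lag
of the two peaks in hours; a negative lag means regulatory load rises
before the transcript does.

**MRE prediction and confirmation.** Candidate miRNA:mRNA sites come
either from an imported miRanda-style table (re-filtered defensively to
score ≥ 140 and energy ≤ −10 kcal/mol) or from the internal seed scanner,
which reports perfect Watson–Crick matches to the miRNA seed (nucleotides
2–8) in *all* transcript regions — 5'UTR, CDS and 3'UTR — classified as
8mer, 7mer-m8, 7mer-A1 or 6mer and reported once per occurrence with the
best class (default reportable floor: 7mer-m8). The scanner is a
documented stand-in for full duplex-scoring predictors: it carries no
alignment score or free-energy model, because the pipeline's contribution
— footprint confirmation — is independent of where raw candidates come
from. A pair is *confirmed* when, separately for each replicate at each
time point, (a) the miRNA is present in that replicate's Ago-short library
at ≥ 100 RPM (raw per-replicate RPM: the floor describes presence in a
library, so normalization does not apply), and (b) the MRE start lies 5–43
nt downstream (3' direction) of the anchor of a footprint with strength
≥ 0.31 RPM/RPKM. All three bounds are inclusive ("minimum of", "at
least", "within 5 to 43"); the footprint "start" is its anchor, the only
position the calling model singles out. The confirmed set is the union
over conditions, with supporting evidence retained per condition.

**Overlap statistics.** Confirmed pairs are collapsed to gene level (a
gene is a target if any of its transcripts is) and each miRNA's target
set is tested for over-representation in an externally defined
regulated-gene set with the one-sided Fisher exact test — the
hypergeometric upper tail P(X ≥ k), computed on the log scale via
`stats::phyper` and cross-checked in tests against both exhaustive
enumeration and `stats::fisher.test` — followed by BH adjustment across
miRNAs. The universe is the caller's choice; the default recommendation is
all genes with RNA-seq evidence at the relevant time point, and gene sets
must be subsets of it (violations are errors, not silent drops).

**ceRNA networks.** For each time point, footprints within 20 bp on a
transcript are merged (transitively; strengths and read counts sum, the
anchor follows the strongest constituent) and replicate-averaged. An mRNA
joins a candidate network when (1) its second strongest distinct footprint
is *less than* 25% of the strongest — strict, as printed conventions go —
and (2) the most loaded miRNA with a confirmed MRE in that footprint is at
least 10× the second most loaded (inclusive; the wording "10x higher" is
ambiguous, so the boundary is a documented choice and unit-tested at
ratios 10.05 and 9.95), using replicate-mean normalized RPM. Single
footprints and single confirmed miRNAs pass vacuously — the "one major
footprint targeted by a single miRNA" case is precisely the target of the
analysis. Per-time-point networks are merged across time points as a set
union keyed by hub miRNA, with per-edge supporting time points retained;
merging is idempotent and order-independent.

## The synthetic-study generator

`generate_study()` produces a complete fake experiment with recorded
ground truth, emulating the study design: 2 replicates × 4 time points;
100 transcripts of 500–3,000 nt with 5'UTR/CDS/3'UTR annotation and random
sequences; 50 miRNAs with baseline loading log-uniform across 10–100,000
RPM, of which ~10% are dynamically recruited with an exact 5-fold change
at one post-quiescent time point (the static pool absorbs the
renormalization so each library's true RPM still sums to one million);
transcript abundances log-uniform across 0.1–1,000 RPKM; 50 planted
footprints (one per transcript, expected depth 30 fragment starts per
library, start jitter normal with sd 2 nt) over a uniform background of
0.005 starts/nt; fragment lengths uniform in 25–50 nt; planted seed-match
MREs written into the sequence 5–43 nt downstream of each anchor, assigned
to RISC-loaded miRNAs; and 25 decoy seed matches planted far from every
footprint. Replicate counts are negative-binomial with dispersion 0.05
(variance = mu + 0.05 mu²), a realistic level of biological variability
for n = 2 designs; dispersion 0 gives Poisson noise for law-of-large-number
checks.

What the generator does *not* emulate: sequencing error, adapter/UMI
artefacts, cross-link-induced mutations, non-uniform background (real CLIP
background follows expression and structure), isoform ambiguity, or
footprint width variation. Passing tests on synthetic data therefore
demonstrate algorithmic correctness under the stated model — recovery of
planted structure, exactness of the filters and statistics — not
performance on any particular real library.

## Numerical choices and degenerate inputs

* Ties in maximal start accumulation: leftmost (5'-most) anchor, for
  determinism; equal-strength footprints resolve to the first by position.
* Threshold boundaries: detection (100 RPM), differential floor (1,000
  RPM), MRE window (5–43), strength (0.31) and miRNA dominance (10×) are
  inclusive; footprint dominance (<25%) and the TRL floor (>1) are strict.
  Every boundary has a dedicated test.
* Zero-count miRNAs keep RPM 0; pseudocounts (0.5 RPM in log-ratios and
  log2 loading, 0.1 in profile matrices) appear only inside logs.
* Fewer than 5 miRNAs above the normalization floor: normalization warns
  and becomes the identity rather than trusting a 4-point median.
* Empty inputs (no fragments, empty clusters, empty footprint lists)
  produce empty, well-typed results; bounds violations and unknown ids are
  errors that name the offender.

## Problem sizes

The validation suite uses deliberately small instances chosen to exercise
every rule while keeping the whole suite quick on one CPU: 1,000 random
start vectors (≤ 500 nt, ≤ 100 fragments) for the caller-oracle
equivalence; a 100-transcript / 50-footprint study at 10:1
foreground:background for anchor recovery (≥ 90% within ±5 nt required,
≤ 10% spurious); the default study for MRE recall (≥ 95% of recoverable
planted pairs; 0% of decoys) and the >10-fold refinement ratio; all
hypergeometric tables with N ≤ 25 against enumeration (agreement within
1e-12); 100 repetitions of a 500-miRNA null loading simulation for FDR
control (empirical per-family false-call rate ≤ 0.25 at the 20% ceiling);
and a 40-profile two-group clustering recovery. `scripts/acceptance.R`
re-runs all of these from scratch under a caller-supplied seed.

## Worked example

```{r example}
study <- generate_study(synthetic_config(seed = 42))
res <- run_clip_pipeline(study$models, study$fragments, study$mirna_counts,
                         study$rnaseq_counts, study$clip_library_sizes,
                         study$mirnas)
length(res$detected)                 # RISC-loaded miRNAs at >= 100 RPM
head(res$differential[res$differential$called, ])
res$refinement                       # raw vs footprint-confirmed pairs
head(res$trl[res$trl$retained, ])
head(res$networks)
```

## Known limitations

* The footprint model is one-dimensional and start-based; it ignores
  fragment 3' ends, coverage shape and cross-link diagnostics.
* Confirmation treats each condition independently; a pair supported once
  in eight conditions carries the same flag as one supported in all eight
  (the support table lets callers impose stricter reproducibility).
* The internal seed scanner deliberately omits thermodynamics,
  conservation and 3'-supplementary pairing; imported predictions should
  be preferred when a full predictor is available.
* The gene universe for overlap statistics is consequential and cannot be
  defaulted safely; published overlap p-values are only reproducible with
  the original universe and target lists.
* With n = 2 replicates, differential-loading power at moderate fold
  changes is limited and miRNAs below the 1,000 RPM floor are untestable
  by design.
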