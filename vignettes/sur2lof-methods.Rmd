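---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sur2lof)
```

This vignette documents the models the package implements, the choices that
were genuinely open, and what the bundled simulators do and do not
represent.

## Discovery pipeline

### Filter semantics

All quality criteria are applied **strictly as stated**, honoring the
stated inequality direction: a proband call is discarded when GQX < 10, variant
read fraction < 0.20, GQ < 30, R8 > 8, SB > −10, or DP < 20. Boundary
values survive (DP = 20 is kept). R8 is a homopolymer-adjacent indel
metric, undefined for substitutions, so the criterion is evaluated on indel
records only; R8 and SB are treated as opaque scores thresholded on the
supplied values. A call missing a required field is *unevaluable*: the
record is removed and counted separately rather than silently passing.

Whole-genome site filtering uses the class-specific hard filters (SNV:
QD < 2, MQ < 40, FS > 60, HaplotypeScore > 13, MQRankSum < −12.5,
ReadPosRankSum < −8, ≥ 3 SNVs in 35 bp; indel: QD < 2, FS > 200,
ReadPosRankSum < −20), and the high-quality genotype predicate DP > 4 ∧
PASS ∧ GQ > 98. The SNV-cluster window is treated as sliding; the window
anchoring is not observable from the filter definition, and the count is
consumed as an annotation rather than recomputed.

Population frequency: a record is removed iff **any** source reports a
frequency above the ceiling (default 1%); absence from every source is
treated as frequency 0 and retained, which is the intended behaviour for
rare-variant discovery (an unobserved allele is the strongest rarity
evidence available).

Coordinates are 1-based inclusive at the interfaces (VCF convention);
interval arithmetic merges regions before membership testing and expands
every interval by the flank (10 bp in panel mode, 100 bp in whole-genome
mode) on both sides. Splice-window membership is a signed-offset predicate:
intronic offsets up to 8 bp and exonic offsets up to 3 bp from the nearest
intron–exon boundary, the boundary-adjacent base being 1.

### Inheritance models

The recessive-homozygous call requires proband 1/1 with both parents 0/1;
a homozygous proband with a homozygous-reference parent is routed to the de
novo check instead. Compound-heterozygous candidates are phased **by
transmission only**: a proband het is assigned a parental origin when
exactly one parent carries the allele, sites where both parents are het are
ambiguous and excluded from pairing (and reported), and a gene qualifies
when it carries at least one maternal and one paternal qualifying het.
Read-backed phasing is out of scope because only genotype data are modelled.
With several affected siblings, candidates are intersected across them by
default; a proband-only mode is provided because it is not observable from
the filter description which convention an external pipeline used.

In the case-only cross-family mode no parental genotypes exist, so the
compound-het analysis degrades to "≥ 2 qualifying hets per gene in each
case", which is an upper bound on true trans configurations; the function
documentation says so explicitly.

### Kinship and homozygosity

The kinship estimator is the KING-robust within-pair form,
φ̂ = (N~het,het~ − 2·N~opposite-hom~)/(N~het,1~ + N~het,2~). It is
allele-frequency-free, standard for sequencing QC, and has clean pedigree
expectations (0.5 duplicates, 0.25 first-degree, 0 unrelated) — those
expectations are the test targets. Pipelines that estimate kinship from
noisy multi-sample calls can center unrelated pairs near 0.05 rather than
0; that offset is a property of their data processing, not of the
estimator, and is deliberately not reproduced.

Shared homozygosity blocks are maximal runs where both samples are
homozygous for the same allele at jointly called sites, with a configurable
number of tolerated interrupting sites (default 0) and a minimum length
(default 1 Mb). Block length is reported as `end − start`, the convention
under which the block chr12:18,326,590–22,176,010 is 3,849,420 bp = 3.8 Mb
at one decimal (the +1 convention rounds to the same value at Mb
precision).

## Exon-skip consequences

All arithmetic is done in cDNA space after mapping genomic coordinates
through the transcript model (strand never enters the arithmetic). The
residue index of cDNA position *n* is ⌈n/3⌉. An internal coding exon
`[c1, c2]` deletes `c2 − c1 + 1` nt; in-frame iff divisible by 3;
codon-aligned iff `c1 ≡ 1 (mod 3)` and `c2 ≡ 0 (mod 3)`, in which case the
protein loses exactly `(c2 − c1 + 1)/3` residues. An in-frame but
codon-straddling skip joins two partial codons into one novel junction
residue; the package annotates this as a deletion plus junction
substitution rather than a pure deletion, because the general case needs
it even though the motivating exon (c.1165–1320) is codon-aligned.
Skipping the initiator exon raises a start-loss error; the terminal exon
has no donor and cannot be "skipped" by a donor variant.

`verify_by_translation()` is the in-package oracle: it translates the CDS
with and without the skipped interval (`Biostrings::translate`), aligns by
longest common prefix/suffix, and reports the residue-level diff. For
in-frame skips, `n_removed − n_inserted` equals the predicted residue loss;
the prefix/suffix alignment is not unique when flanking residues repeat, so
property tests compare counts, not interval positions, on random
sequences.

## Channel assays

### Efflux rates

Cumulative efflux is plain count arithmetic:
fraction(tᵢ) = Σ released up to tᵢ / (Σ released + lysate). Rate constants
are fitted only on the 2.5–12.5 min window because cumulative efflux
diverges from a single exponential at later times; the package honours the
window restriction and does not model the divergence. Fits are
sum-of-squares on the fraction scale, initialized from the exact
log-linearization `k₀ = mean(−log(1 − y)/t)` and polished by bounded
Levenberg–Marquardt (`minpack.lm::nlsLM`) with the rate bounded below at 0
(or at the fixed k₁ for the two-rate model) — nonnegativity is enforced by
the optimizer, not by post-hoc clipping. Replicates are pooled into one
fit by default. The all-zero series is handled analytically (k = floor).

### Dose–response

Currents are normalized to the basal current in nucleotide-free solution,
fixing Imax = 1, leaving three free parameters (Imin ∈ [0, 1], IC₅₀ > 0,
H > 0) estimated by bounded least squares. IC₅₀ is initialized at the
geometric mean of the concentration range and H at 1, which converges
reliably for monotone data; non-convergence is reported as a warning on
the returned fit rather than an error.

### Simulator conditions

`simulate_efflux()` uses the five collection times 2.5, 5, 12.5, 22.5,
37.5 min, six replicate wells, and multiplicative log-normal count noise
(cv 0.05, mean-one). `simulate_dose_response()` spans 1 µM–10 mM in
half-decade steps — the top of the series is the fully inhibiting
concentration the assay itself applies, which is what makes the Imin
plateau identifiable — with five replicates per concentration and additive
noise of 0.015 on the normalized-current scale, a scatter consistent with
normalized patch-clamp measurements. Under these conditions the median
relative recovery error of k₁, k₂, IC₅₀, H and Imin across 200 seeded
simulations stays below 5%, and noiseless data are recovered to ≤ 10⁻⁶
relative (rates) / 10⁻⁴ (Hill parameters). Default Imin is 0.1: a small
residual unblocked current is typical for ATP inhibition and keeps
relative error well defined.

### Expression and patch currents

Relative expression uses the Pfaffl ratio
E~target~^ΔCt,target^ / E~ref~^ΔCt,ref^ with ΔCt = mean calibrator Ct −
sample Ct; amplification efficiencies default to 2 (reducing to 2^−ΔΔCt^)
because no measured efficiencies are available. K_ATP current is the
difference between nucleotide-free and fully inhibited current; the
declared fully inhibiting concentration is configurable (10 mM MgATP for
mouse, 5 mM ATP for zebrafish myocytes) and applying a lower concentration
is an error, not a warning, since the difference would underestimate the
current.

## Physiology metrics

Ventricular volume is computed **verbatim** as V = 4/3·π·a·b². Whether the
measured a, b are full axis lengths or semi-axes only changes a constant
factor (8×) that cancels in SF, FAC, EF and in any between-group
comparison; a semi-axis mode (π·a·b²/6) is available. EF uses the
universal definition (EDV − ESV)/EDV × 100.

Heart rate is measured over consecutive triplets of inter-beat intervals
and averaged, mirroring triplicate manual measurement. The ventricle
simulator quantizes the beat period to an even number of frames so that
end-diastole and end-systole fall exactly on annotated frames; the realized
rate (reported in the truth ledger) is the test target, which is what makes
machine-precision recovery a meaningful assertion.

Locomotor summaries: frame speeds below 2 mm/s are inactivity (system
noise) and contribute no distance; movements are small below 10 mm/s.
The threshold separating intermediate from high-speed movements has no
published numeric value; the default of 20 mm/s is a package default,
clearly so documented, and configurable. Integration bins are 30 s.
Inverted-screen trials cap at 180 s and sum over six trials. The
six-minute-walk reference equations are evaluated with their published
coefficients exactly as written; tests freeze values recomputed from those
coefficients.

## What the simulators do and do not emulate

The cohort generator produces: two nuclear families (defaults: four
affected children; two affected plus one unaffected) with trio-consistent
genotypes; a rare-skewed Beta background frequency spectrum on 0–0.5; a
causal variant planted homozygous in every affected individual and
heterozygous in all parents, inside a shared homozygous founder block
(defaults use the real coordinates chr12:18,326,590–22,176,010 and
chr12:22,063,090 C>T); block-tagging sites with *common* frequencies and
silent effects, so they are removed by the frequency/effect filters rather
than by construction; and a configurable fraction of records planted to
fail each quality criterion, so every filter is exercised in both
directions. The causal site itself is generated as a clean, well-covered
call in every sample — its discoverability is part of the planted truth.
A truth ledger (causal id, block bounds and sites, de novo ids, seed)
accompanies every cohort.

Not emulated: linkage disequilibrium outside the planted block, sequencing
error modes correlated across samples, multiallelic sites (the pipeline
consumes decomposed records only), population structure, and annotation
error. Passing recovery tests on this cohort therefore demonstrates that
the pipeline's logic is correct under its stated assumptions, not that the
filters are robust to real-data artefacts those assumptions exclude.

All simulators draw from one seeded generator per run and restore the
global RNG state afterwards; identical spec + seed gives byte-identical
serialized output.

## Problem sizes used by the test suite

The shipped tests run a 4,000-background-variant two-family cohort plus a
300-variant cohort for brute-force-oracle comparisons, 10,000-SNP panels
for kinship recovery, 200 seeded noisy simulations per assay for parameter
recovery, and 1,000 random transcripts against the translation oracle —
sizes at which the exhaustive oracles remain exact and the whole suite
completes in about a minute.

## Known limitations

- Compound-het candidates in case-only mode overcount true trans pairs.
- The ROH scan assumes jointly called, position-sorted sites; it does not
  impute across missing calls beyond the configurable tolerance.
- Effect classification covers substitutions and simple indels against a
  single transcript; it is not a general-purpose annotator.
- The efflux model ignores the late-time divergence from
  mono-exponential kinetics by design (window restriction).
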