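---
title: "Mapping m1A in tRNA fragments from RT misincorporation signatures"
author: "trfm1a package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping m1A in tRNA fragments from RT misincorporation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfm1a)
```

## The problem

N¹-methyladenosine (m¹A) sits on the Watson–Crick face of adenosine, so a
reverse transcriptase that encounters it either stalls or reads through
while misincorporating a wrong base. Both behaviors are informative: the
misincorporation produces a position-specific mismatch signature in
sequencing reads, and the stalling makes modified molecules
under-represented in libraries made with stall-prone enzymes. This package
implements the computational side of a small-RNA m¹A mapping workflow
built on those two signals plus antibody (RIP) enrichment, with a
particular focus on tRNA-derived fragments: the 22-nt 3′ fragments
(tRF-3b) carry the tRNA's m¹A58 inside their seed region (fragment
position 4), where the modification can interfere with Ago-loaded
seed pairing and hence with gene silencing. The final stage of the
workflow therefore scores seed-matched target genes for coordinated
repression or de-repression.

Everything runs on synthetic data generated by the package itself, with
complete ground truth, so each stage is testable at desk scale.

## Coordinate conventions

All coordinates are 1-based and inclusive, on the mature tRNA *including*
the post-transcriptionally added 3′ CCA. A 3′-anchored fragment of length
`f` on a parent of length `L` places fragment position `i` at mature
position `L − f + i`; 5′-anchored fragments map identically. "A58" is a
property of the annotation of a specific tRNA, not a hard-coded number:
the generator places the site at `L − 18`, which is position 58 for the
canonical `L = 76` and is always position 4 of the 22-nt 3′ fragment.
Sequences are stored in the DNA alphabet (U→T), matching sequencer output.

## The RT error model

`rt_model()` describes an enzyme by four quantities:

| parameter | meaning | TGIRT | PSII | RT-1306 |
|---|---|---|---|---|
| `p_mis` | P(misincorporation at a modified base) | 0.85 | 0.05 | 0.70 |
| `p_stall` | P(truncation at a modified base) | 0.05 | 0.90 | 0.10 |
| `eps_bg` | per-base background substitution | 0.002 | 0.005 | 0.005 |
| `mis_spectrum` | substituted-base distribution | uniform C/G/T | — | — |

The background 0.2% for TGIRT reflects its characteristic low error floor;
the remaining preset numbers are configuration defaults shaped by the
qualitative read-through/stall behavior of the three enzymes, not fitted
constants, and all are overridable. The spectrum defaults to uniform over
C/G/T because only the aggregate A→C/G/T behavior matters downstream.

Stalling removes the molecule entirely — no truncated read is emitted —
because in a ligation-first protocol (both adapters ligated before cDNA
synthesis) a truncated cDNA lacks the 5′ priming site and can never be
amplified. This single design choice reproduces the under-representation
of m¹A-containing RNAs in stall-prone libraries without modeling
truncation products. It yields a closed form used throughout the tests:
among emitted reads, the mismatch rate at a site of stoichiometry `p` is

```
m(p) = p*p_mis/(1 - p*p_stall) + (1 - p*p_mis/(1 - p*p_stall))*eps_bg
```

exposed as `expected_mismatch_rate()`. One subtlety worth knowing: the
closed form describes the emitted reads, while the measured index is
computed after mapping, and a read carrying both the site misincorporation
and a background error elsewhere exceeds the 1-mismatch mapping budget and
drops out. The induced depression is bounded by `(L-1)*eps_bg` of the
attributable rate (about 4% relative at TGIRT defaults) and the test suite
accounts for it explicitly rather than pretending it away.

## The synthetic-data generator

`build_reference()` draws mature tRNAs (72–90 nt, CCA-terminated, nuclear
m¹A at `L − 18`, mitochondrial tRNAs with m¹A at position 9), poly-U-ended
trailers, miRNAs, and spike-ins that are rejected and redrawn until they
share no 15-mer with any biological reference (so they can never
cross-map). `simulate_fragment_pool()` enumerates exact fragment species —
22-nt and 18-nt tRF-3 suffixes, tRF-5 prefixes (18 nt), 5′ halves (34 nt),
trailer tRF-1s, full miRNAs and spike-ins — and draws copy numbers
multinomially from a class profile defaulting to a tRF-3b-heavy mix
(30% tRF-3b, 12% tRF-3a, 15% tRF-5, 8% tRF-1, 5% halves, 25% miRNA, 5%
spike-ins), chosen once as a plausible small-RNA composition in which
every class has enough reads to be analyzed. Modification status is
Bernoulli(`p`) per molecule per annotated site; the default stoichiometry
0.8 reflects the high-stoichiometry regime typical of tRNA T-loop m¹A.
Calibration mixes follow the stated benchmark grid of 0/20/40/60/80/100%
modified oligo.

`simulate_rip()` multiplies a molecule's sampling weight by
`enrichment_factor` (default 8) in the antibody arm iff it carries at
least one modified site, and samples the IgG arm at a nonspecific
`igg_capture` fraction (default 0.25) of the library depth. With spike-in
normalization the planted 8× preference is recovered as log2 fold
enrichment ≈ 3.

What the generator deliberately does **not** emulate: adapter/UMI
artifacts, PCR duplication, quality-score error profiles, indels,
overdispersed (negative-binomial) counts, antibody off-target capture
(e.g. cap-m⁷G cross-reactivity), and — importantly — the strong seed-sequence
similarity of real tRF-3bs. Random tRNA 3′ ends produce mostly distinct
seeds, so the "few seed families cover most of the guide pool" phenomenon
of real data does not arise in simulation; the seed-clustering machinery
is exercised on constructed counts instead. Passing tests therefore
demonstrate correctness of the computations under a clean generative
model, not robustness to every artifact of real libraries.

## Mapping policy and tRF taxonomy

Reads of 15–50 nt are collapsed to unique sequences and mapped
hierarchically: miRNA space first (up to 2 non-templated 3′ bases soft
clipped, 1 internal mismatch), then tRNA space (mature + trailers; 1
mismatch, 0 indels, no clipping), then spike-ins. A read with any hit in
an earlier category is never searched in later ones, and its hits share
equal fractional weight so multi-mapping reads (common across
isodecoders) are counted exactly once. The aligner itself is a transparent
exact-candidate + Hamming-verification scheme: with at most one
substitution and no indels, one of two disjoint 6-mer anchors at the read
5′ end must be error-free, so a k-mer hash enumerates every candidate
placement; an exhaustive brute-force oracle in the test suite confirms
exact agreement. The reference space is a few kilobases, so no genome
aligner or BAM machinery is warranted; a documented TSV is the interface.

Classification: tRF-3 requires the alignment to end exactly at the mature
3′ terminus (full CCA — reads stopping at CC are `other`, keeping the
fragment-position-4 frame unambiguous); tRF-5 starts at position 1; tRF-1
starts at position 1 of a trailer. End-anchored fragments of ≥ 30 nt
become halves — the cutoff is stated as 30 nt and the boundary side was
open, so ≥ 30 was chosen to make "30-nucleotide" the first half length.
tRF-3s of exactly 22/18 nt are isoforms 3b/3a.

## Mismatch statistics

Pileups accumulate fractional-weighted coverage and per-base substitution
counts, in either the fragment frame (where all tRF-3bs pool at positions
1–22) or the mature frame. The mismatch index is 100 × mismatches /
coverage, and is *undefined* — never zero — when coverage is ≤ 50 reads;
undefinedness propagates through every downstream comparison with an
explicit reason. Cross-condition comparisons (e.g. writer-enzyme
knockdown) report the index difference and a pseudocounted log2 ratio; the
pseudocount of 0.1 percentage points is an artifact decision (none is
stated in the underlying methodology) and only matters near zero rates.
The normalized mismatch index, `value/(100 − value)`, grows without bound
as a site saturates and is flagged infinite at exactly 100%.

## Calibration

`fit_calibration()` regresses observed mismatch% on known stoichiometry%
through the origin, as in the synthetic-oligo benchmark. R² uses the
uncentered convention `1 − Σ(y−ŷ)²/Σy²` — the convention `summary.lm`
applies to intercept-free fits — stated explicitly because centered R² is
misleading when the intercept is suppressed. Background (the mismatch rate
of the unmodified oligo) is *not* subtracted inside the fit, mirroring the
forced-zero benchmark fit; it enters only when inverting the curve.
`estimate_stoichiometry()` clamps `(observed − background)/slope` to
[0, 1] and attaches a percentile bootstrap CI over read resampling
(1000 resamples, seed-controlled). Because the zero-forced fit absorbs the
mild stall-induced curvature, inversion at TGIRT defaults is nearly
unbiased (the suite checks |bias| ≤ 0.05 across the 20–100% grid at 10⁴
reads). Sequence-context-specific calibration curves are out of scope.

## Enrichment testing

Per-RNA RIP-vs-input enrichment is tested at the (parent, class, isoform)
group level with a two-sided exact binomial test of the RIP count against
the combined count, null proportion equal to the RIP share of combined
library depth, Benjamini–Hochberg adjusted, with records under 10 combined
counts excluded. This deliberately replaces a negative-binomial engine:
the simulator's multinomial counts carry no extra-Poisson dispersion, so
the binomial test is calibrated here (checked empirically), while real
overdispersed data would need the heavier machinery — a documented
simplification, not a claim of equivalence. Thresholds default to the
workflow's padj < 0.1 for candidate calling and 10⁻⁵ for volcano-style
coloring. Fold enrichment uses RPM with a 0.5-RPM pseudocount, switching
to spike-in-normalized frequencies when QC spike-ins are present — the
right denominator in RIP arms, where antibody capture distorts the mapped
total.

A group is called an m¹A **candidate** only on the intersection of
evidence: significantly enriched (padj below the cut, positive log2 FE) in
*every* antibody arm, not significant in the IgG arm, and carrying a
defined mismatch index above 10% at an annotated site. The 10% evidence
threshold is an artifact decision standing in for qualitative judgment.

## Seed families, target sites and repression

Seeds are guide positions 2–8 (7 nt) for both clustering and UTR
scanning. The source methodology mentions positions "1–8" in one place
and "2–8" in another; the 2–8 convention is implemented throughout and
the discrepancy is surfaced here rather than silently resolved. Site
types on the mRNA, written 5′→3′ with `core7 = revcomp(seed)`:
8mer-A1 (`core7` + A), 7mer-m8 (`core7`, no A), 7mer-A1 (`core6` + A, not
part of a `core7` match), 6mer (`core6` alone). The "A1" adenosine is the
mRNA base opposite guide position 1, per the standard microRNA target-site
convention. Each core6 occurrence resolves to exactly one (highest) type,
and genes are labeled by their best site; a brute-force oracle working in
guide–target pairing space verifies the scanner exactly.

Only genes with a 3′ UTR and expression strictly above 100 normalized
counts enter the CDF analysis; everything else is excluded entirely
(neither target nor non-target). Log2 fold changes are centered by the
non-target median, and each class is compared to non-targets with a
one-sided two-sample Kolmogorov–Smirnov test. Direction ("repressed" for
the knockdown arm, "derepressed" for the tumor-style arm) is always an
explicit argument, never inferred from the data. No multiplicity
adjustment is applied across the ≤ 4 class tests — per-class p-values are
reported as such, noted in the output metadata. Classes under 10 genes
report `NA` rather than an unstable p-value.

## Numerical and reproducibility choices

Every stochastic operation takes an explicit seed and the pipeline refuses
configurations with missing stage seeds; fixed seeds give byte-identical
FASTA/FASTQ/TSV outputs, and every result table carries an md5 hash of the
configuration. Reads are collapsed before alignment; weights, not copies,
flow through counting and pileups. Ties and degenerate inputs are handled
explicitly: empty profiles warn and return empty objects, zero spike-in
denominators abort naming the library, saturated mismatch indices flag
infinity, and an observed mismatch below background clamps the
stoichiometry estimate to zero with a warning.

The test suite runs on deliberately small problem sizes chosen to keep the
whole suite in the minutes range while leaving comfortable statistical
margins: pools of 4–30 thousand molecules for localization and recovery
checks, 10⁵ molecules where the closed-form convergence is asserted, 10⁴
reads per calibration level, 200-seed simulations for K-S level and power
(n = 300 planted targets, δ = −0.5, σ = 0.4), and 100-seed false-call
control at enrichment factor 1. Bootstrap intervals use 1000 resamples.

## Known limitations

* The mismatch signature cannot distinguish m¹A from any other
  substitution-inducing modification on its own; the antibody arm carries
  that burden, and antibody cross-reactivity is not modeled.
* Stoichiometry inversion assumes the calibration oligo's RT behavior
  transfers to the measured fragment; sequence context effects on the
  misincorporation rate are real and unmodeled.
* The binomial enrichment test is anti-conservative on overdispersed real
  count data; swap in a negative-binomial engine for biological replicates.
* Non-templated 3′ tails are treated as pure artifact bases (miRNA
  category only) and never matched against genomic sequence.
* The simulator's clean multinomial sampling understates the variance of
  real libraries; recovery margins observed here are upper bounds on what
  real data would give.
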