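---
title: "Dating endogenous retrovirus insertions from LTR divergence"
author: "ervclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating endogenous retrovirus insertions from LTR divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(ervclock)
  library(Biostrings)
})
```

## The model

An endogenous retrovirus (ERV) is a germ-line retroviral integration. The
provirus that integrates carries two long terminal repeats (LTRs) that are
*identical* at the moment of integration, because both are synthesized from
the same template during reverse transcription. Once the element is fixed
and silenced, each LTR accumulates substitutions independently and neutrally.
The divergence $D$ between the 5' and 3' copies of one insert therefore
measures twice the time since integration:

$$T \;=\; \frac{D}{2R},$$

where $R$ is the neutral substitution rate per site per year. The factor of
two is the crux of the method: divergence accumulates on *both* copies.

$D$ is estimated with Kimura's two-parameter (K2P) correction, which
distinguishes transitions (A$\leftrightarrow$G, C$\leftrightarrow$T,
proportion $P$ of compared sites) from transversions (proportion $Q$):

$$\hat D = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q),$$

with the standard delta-method variance
$\big(c_1^2 P + c_3^2 Q - (c_1 P + c_3 Q)^2\big)/n$ where
$c_1 = 1/(1-2P-Q)$, $c_2 = 1/(1-2Q)$ and $c_3 = (c_1+c_2)/2$. Saturation
(either logarithm undefined) is reported as an explicit error, never as NaN.
Sites with a gap or an N in either copy are excluded pairwise, because the
correction assumes unambiguous aligned bases.

Because the neutral rate of felid ERV LTRs is unknown, every divergence is
dated under a panel of three published rates rather than a single clock:
two human-ERV-derived rates ($2.3\times10^{-9}$ and $5\times10^{-9}$
substitutions/site/year) and a general felid nuclear rate
($1.2\times10^{-8}$). The three ages bracket the plausible integration time:

```{r panel}
dateWithRatePanel(0.084)
```

## Finding proviruses

`findLTRPairs()` looks for the structural signature of a provirus: two
direct repeats of 100–1,500 bp separated by 3–12 kb, with global-alignment
identity at least 0.70. The primary engine is seeded k-mer self-matching
(default $k = 15$): exact k-mer pairs at provirus-like separations are
chained per diagonal, extended along the diagonal while a 31 bp match
window stays above 0.55, and snapped to terminal `TG`...`CA` when both
copies carry the motif nearby. Because two repeat copies at high divergence
occasionally share no exact 15-mer at all, a fallback engine performs an
exhaustive windowed self-comparison over every plausible separation (C++,
100 bp window, 0.55 match-density floor) whenever seeding yields nothing.
Random sequence matches itself at about 0.25 per site, so the 0.55 floor is
several standard deviations above background and insert-free contigs emit
nothing; the suite checks this on seeded 50 kb backbones.

Design points worth knowing:

* **Identity floor 0.70.** This corresponds to divergence roughly 0.4, a
  comfortable margin above the oldest divergences the method is asked to
  date (up to ~0.28). It is a *call acceptance* threshold, not a search
  limitation: short (200 bp) repeats at expected divergence 0.30 have a few
  percent probability of realizing an identity below 0.70 and are then
  rejected by the floor. Lower `minIdentity` to chase older elements, at
  increasing risk of spurious repeat pairs.
* **Span window 3–12 kb** generalizes the canonical ~7–11 kb full-length
  provirus so partially degraded elements are not silently missed;
  `ltrScanConfig(strict = TRUE)` restores the strict window.
* **Strand.** Direct-repeat detection is orientation-symmetric, so the scan
  runs once on the forward strand; the strand of the call is inferred from
  hallmark-motif evidence (TG/CA termini, AATAAA) on the two orientations
  and coordinates are always reported on the forward strand.
* **Boundary convention.** Where the alignment-extent boundary and the
  TG...CA motif boundary disagree by more than 10 bp the call is flagged
  (`boundary_convention_disagreement`) rather than silently resolved.
* **Target-site duplications** (identical 4–6 bp flanks) are reported as
  evidence but never required — real TSDs decay with age.

`callProvirus()` then extracts the internal region, collects six-frame
stop-to-stop ORFs of at least 80 codons, checks gag–pol–env order
(positionally, or by translated similarity when a pol reference is given),
computes the LTR K2P divergence, and dates it under the rate panel.

## Scoring coding decay

Fixed proviruses decay; the tabulated signal is the number of nonsense
(premature stop) and frameshift (indel of length not divisible by 3)
mutations in the *pro/pol* region relative to an intact reference protein.
`countDefects()` aligns the nucleotide query to the reference in codon
space with frameshift-aware moves: a reference residue may consume 3 nt
(clean codon), or 1/2/4/5 nt under a single frameshift penalty. Only these
moves change the reading frame, so every net frame disruption inside the
aligned region is forced through a counted event. Query end gaps are free,
so the whole internal region can be scored directly and the gene is located
by the alignment itself.

Counting rules, chosen to be deterministic and testable:

* A maximal run of frame disruption is one frameshift event. Compensating
  indels separated by at least one intact codon count separately; a
  compensated pair confined to adjacent codons leaves the frame intact
  outside a two-codon window and is — correctly, under the optimal
  alignment — reported as substitutions rather than as frameshifts. (The
  merge rule that would collapse adjacent shift moves into one flagged
  event is implemented for the alignment paths that do produce them.)
* Stops inside frameshifted codons are artifacts of the indel and are not
  double-counted as nonsense; stops downstream of a frameshift are counted
  in the frame the alignment assigns, keeping the two counts independent.
* An aligned stop is penalized four times as hard as an ordinary mismatch,
  which keeps shifted runs from being absorbed into substitution-only
  explanations.

`summarizeDefects()` reports the per-lineage integer median (lower median
for even counts) and [min–max] range, the form in which decay is
conventionally tabulated.

## Lineage delimitation

ERV lineages are delimited on a pairwise distance matrix
(`distanceMatrix()`, p-distance, K2P, or amino-acid p-distance):

* `neighborJoining()` is a from-scratch Saitou–Nei implementation (ties on
  the Q criterion broken by the lexicographically smallest label pair,
  negative branch estimates clamped to zero and flagged). For any additive
  matrix it recovers the generating tree exactly; the suite verifies this
  against path-distance oracles on random trees up to 8 taxa and against an
  independent implementation off additivity.
* `cutLineages()` applies the ">15% divergence between lineages" rule as
  single-linkage clustering at threshold 0.15 — the unique linkage for
  which "no between-lineage pair below the threshold" is guaranteed by
  construction.
* `trimBlocks()` re-implements conserved-block alignment trimming at the
  published option set (minimum block 5, "gap allowed with half" — columns
  with $\ge 50\%$ gaps excluded, bounded runs of nonconserved columns,
  blocks trimmed to conserved flanks). It targets the published
  column-classification logic, not bit-compatibility with any particular
  binary.
* `hitFilter()` curates homology-hit tables with the standard thresholds
  (identity $\ge 30\%$, coverage $\ge 70\%$, e-value $\le 10^{-3}$) and
  collapses same-species near-duplicates ($\ge 95\%$ identity). Hit tables
  carry no sequences, so mutual identity between subjects cannot be
  recomputed; rows sharing species and query at near-ceiling identity are
  treated as redundant and the lowest-e-value representative is kept.

## The simulator and what passing tests mean

`simulateProvirus()` is the package's ground-truth instrument. One
ancestral LTR is constructed with all hallmark motifs (TG...CA termini,
AATAAA in the 3' half, an AT-rich 20-mer in the 5' half), duplicated, and
each copy evolved independently for $R \cdot T$ expected
substitutions/site under a continuous-time K2P process — exactly the model
the dating relation assumes, so expected pairwise LTR divergence is $2RT$.
The internal cassette carries designed gag/pol/env ORFs separated by
spacers with stops in all three frames; a configurable number of nonsense
codons and single-base indels is injected into pol at recorded positions
(at least 10 codons apart, so injected ground truth is unambiguous); the
cassette is flanked by a target-site duplication and embedded in a random
host backbone. All randomness flows from one integer seed.

Defaults describe one realistic study condition and are set once: 450 bp
LTRs, 7 kb internal region (whole element ≈ 7.9 kb), integration
$10^7$ years ago at $5\times10^{-9}$ substitutions/site/year,
$\kappa = 2$ (a conventional mammalian transition bias; never stated for
felid ERVs), 5 bp TSD, 20 kb backbone at 42% GC.

What the simulator deliberately does **not** emulate — and hence what
passing tests do not show about real genomes: indel evolution in LTRs
(observed LTR length differences between copies are not reproduced; the
copies stay length-matched), substitution accumulation in the internal
region (decay is represented solely by injected defects, keeping defect
truth exact), rate heterogeneity along the sequence, nested insertions,
solo-LTR formation, and low-complexity/repetitive host sequence. Detection
performance on real assemblies, where tandem repeats and segmental
duplications mimic direct repeats, will be worse than on simulated
backbones; the identity floor, span window and ORF checks are the defenses.

## Numerical choices

* Coordinates are 1-based closed (`IRanges`) everywhere; GFF3 output is
  therefore an identity mapping, eliminating the usual off-by-one boundary.
* Alignment scoring defaults to match +1, mismatch −1, gap open −5, gap
  extend −1 (a gap of length $L$ costs $-5 - L$); deterministic tie-break
  is delegated to the alignment engine.
* Ages are exact internally (`T_years = D/(2R)` with no rounding); only
  the report layer rounds (3 significant figures for ages, 3 decimals for
  distances), and report age columns are recomputed *from the printed
  divergence* so re-dating a report's D column reproduces its own age
  columns exactly.
* p-distance standard errors are analytic by default
  ($\sqrt{p(1-p)/n}$); a seeded multinomial site bootstrap is available.
  The published difference counts are carried in reports but never used to
  invert K2P: printed divergences are authoritative (printed counts and
  repeat lengths are not mutually consistent in the source tables).
* Problem sizes in the test suite (e.g. 100 dating replicates at 600 bp,
  200-replicate mutator calibrations, 100 random NJ trees) are chosen so
  the statistical assertions have comfortable margins while the whole
  suite runs in minutes.

## A worked example

```{r worked}
sim <- simulateProvirus(simulationParams(trueAge = 5e6, rate = 5e-9, seed = 11))
pairs <- findLTRPairs(contigSeq(sim))
call <- callProvirus(contigSeq(sim), pairs[[1]], polReference(sim))
call
ages(call)
```

The true age is 5 MY at the middle rate; the middle row of `ages(call)`
is the matching estimate, and the outer rows show how the rate panel
brackets it.

## Known limitations

* Exact-seed detection plus the windowed fallback is deterministic down to
  the identity floor, but the floor itself rejects short, very old repeat
  pairs whose realized identity drops below 0.70.
* The K2P SE (and therefore the age interval) ignores alignment
  uncertainty; for diverged LTRs the alignment is taken as given.
* Single-linkage lineage cutting is order-independent but chains: one
  intermediate sequence can merge two otherwise-distinct lineages. That is
  the price of the guarantee that no between-lineage pair sits below the
  threshold.
* Reference-free defect scanning (longest-ORF mode) is not comparable to
  reference-based counts and is not used in reports.
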