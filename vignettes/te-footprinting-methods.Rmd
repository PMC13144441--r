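---
title: "Consensus-anchored TE footprinting: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-anchored TE footprinting: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tefoot)
```

## The problem

Transposable-element (TE) families such as the MaLR LTRs (ORR1A0, ORR1A1)
and MERVL's MT2_Mm are transcriptionally activated at zygotic genome
activation (ZGA) in the mouse embryo, but which transcription factors (TFs)
drive them is largely unknown. Individual genomic copies of a family are too
repetitive for conventional per-locus footprinting, but they share a common
ancestor: the family consensus sequence. `tefoot` exploits this by pooling
bulk ATAC-seq Tn5 insertion events from all *length-intact* copies of a
family into a single meta-profile in consensus coordinates, where protein
occupancy appears as a localized depletion of insertion frequency against
accessible flanking signal. The sequence under each depletion is then
matched against a PWM library, and candidate TFs are filtered by whether
they are actually expressed when the elements are active (every mid- and
late-2-cell cell, in the embryonic application).

## Pipeline model

1. **Intact-copy selection.** A copy is intact when its annotated length
   equals the family's consensus length within `tolerance_bp` (default 0 —
   a literal reading of "corresponds to the consensus length"; real
   RepeatMasker annotations fragment insertions, so the tolerance is
   exposed). Only intact copies admit the linear projection
   `consensus_pos = pos - start` (plus strand) or `(end - 1) - pos` (minus
   strand); no per-copy realignment is attempted, so the projection is a
   bijection and exactly invertible. L1-style 5'UTR monomers are annotated
   separately by an exhaustive ungapped Hamming scan of the monomer
   consensus over both strands (`place_monomers`, default 2 mismatches),
   resolving same-strand overlaps in favour of the lower-distance, then
   leftmost, hit.

2. **Insertion meta-profiles.** Fragments yield two cut sites each
   (`start + 4`, `end - 1 - 5` by default — the standard Tn5 9-bp-duplication
   correction; the shifts are flags since upstream tools differ). Cuts
   falling in an intact copy (half-open containment) increment their
   projected consensus position; the raw count vector is scaled to
   insertions per million *genome-wide* library insertions, so profiles are
   depth-invariant (duplicating every fragment changes nothing) while raw
   sums remain exact event counts.

3. **Footprint calling.** The published detection is explicitly visual; the
   package formalizes it. On the smoothed profile (centred moving average,
   window 3 bp, edge-truncated), position *i* is *depleted* when its value
   is below `(1 - d_min)` times the local background — the mean over two
   25-bp flanking windows starting just outside a `floor(w_min/2)`
   exclusion zone. Maximal depleted runs are merged across gaps shorter
   than `w_min/2`, kept when their width lies in `[w_min, w_max]` = [6, 30]
   bp (the span of TF binding sites) and the interval's flank mean is at
   least `c_min` = 0.5 per million (suppressing calls in dead regions).
   Each kept interval gets the depletion statistic
   `D = (m_flank - m_center) / m_flank` (1 = complete protection, 0 = no
   footprint, `D = 0` by convention when `m_flank = 0`). `D` is invariant
   to rescaling the profile by any positive constant, and calls mirror
   under profile reversal; both properties are asserted in the tests, and
   the caller is checked against an exhaustive independent reference on
   random short profiles. Footprints are called per stage, unified across
   stages (intervals with ≥ 50% reciprocal overlap merge to their union),
   and every unified interval is scored on every stage; a stage is
   "present" when `D ≥ d_min` (default 0.3), giving stage-specificity
   labels such as `early2C+late2C`.

4. **Motif matching.** The footprint's consensus sequence (padded 3 bp,
   both strands) becomes a smoothed one-hot probability matrix
   (`(one_hot + c) / (1 + 4c)`, `c = 0.1`; ambiguity codes become uniform
   columns). It is slid ungapped across each library PWM; the score at an
   offset is the mean over all query columns of the Euclidean column
   distance, with overhanging query columns scored against the uniform
   column — a width-invariant distance that penalizes spurious partial
   overlaps (minimum overlap 4). The analytic null of the original
   Tomtom-style comparison is replaced by a permutation null: pseudo-targets
   of the same width with columns resampled from the pooled library
   columns, `p = (1 + #\{null ≤ d\}) / (n_perm + 1)` with `n_perm = 999`,
   and `E = p × library size`. Matches with `E < 30` are retained — the
   published threshold, which at desk-scale library sizes is deliberately
   permissive; the expression filter downstream does the discriminating,
   exactly as in the original design. The p-values are uniformly calibrated
   against decoy-only libraries (asserted by a KS test), and lower
   distances never receive larger p at a fixed seed.

5. **Candidate filtering.** Matched TFs are kept when their *raw* count is
   ≥ 2 in every cell of the filter stages (mid2C, late2C) — raw, because
   the rule is phrased in reads; reported expression values use rpm
   (counts / column sum × 1e6). Per-family candidate lists are the unique
   TF names across footprints and strands; the merged list is their union,
   and `venn_counts` reports exclusive intersection-region sizes. No
   multiple-testing correction is applied at this stage, matching the
   published procedure (E-threshold plus expression rule only).

6. **Binding integration.** A bedGraph signal track (e.g. CUT&Tag) is
   summarized over intervals with deeptools-style geometry: `scale-regions`
   (body resampled to equal bins with fractional-overlap length-weighted
   means, fixed-width flank bins, minus-strand rows reversed) and
   `reference-point` (fixed window, ±1 kb in 10-bp bins by default). Bin
   values are means with 0-fill for uncovered or off-chromosome positions
   (flagged) — the mean-vs-sum and missing-data conventions are not
   recorded for the original matrices, so this is the package's documented
   choice. "Bound" insertions are the top 25% of rows by full-row sum
   (stable ties; flank exclusion available upstream by passing
   `flank_bp = 0`). Genes are "near" an insertion when the TSS-to-interval
   gap distance is ≤ 10 kb, boundary inclusive, 0 inside. Group
   log2-fold-change comparisons use a two-sided unpaired t-test — Welch by
   default because group variances are unmodelled, with a pooled-variance
   flag since the original analysis does not specify the variant.

## What the synthetic generator emulates

`default_sim_config()` fixes the reference study conditions: a 150-kb toy
chromosome carrying two 300-bp TE families with 50 intact plus 10
3'-truncated copies each, placed uniformly without overlap on random
strands, each copy mutated at 2% per base except at planted sites. Five
15-bp TF binding sites (three in family 1, two in family 2) carry centred
10-bp motifs (sharp 0.85-probability PWMs) and are occupied at 2-cell
stages. Tn5 cut sites are Poisson per position with relative rate 1 outside
elements, 10 inside (accessible elements), multiplied by the protection
factor ρ = 0.15 inside an occupied site at its occupied stage; 18,000
expected insertions per stage yield ≈ 20 aggregated insertions/bp over the
50 intact copies of a family — enough that a ρ = 0.15 site drops well below
the `d_min = 0.3` calling threshold with Poisson noise. The motif library
adds 25 flat-Dirichlet decoys (widths 6–12) to the 5 planted motifs;
expression draws Poisson(30) for planted TFs (rejection-resampled to
guarantee ≥ 2 in mid/late-2C cells, where Poisson(30) fails that bound with
probability < 1e-5 anyway) and Poisson(1) for decoys, which therefore fail
the filter essentially always. Everything is deterministic given the master
seed, to the byte.

The generator deliberately omits: Tn5 sequence bias, sequencing error,
duplicate reads, nucleosome positioning, fragment-length structure (cut
sites are generated directly; a converter pairs them into pseudo-fragments
so the fragment-input path is testable), and insertional polymorphism.
Passing tests therefore demonstrate the pipeline's correctness and
calibration under an idealized insertion model — not robustness to the
biases of real ATAC libraries, where bias-corrected callers and curated
annotations remain necessary. ρ is a calibration choice, not a measured
quantity: no quantitative depletion depth is available for the real
footprints.

## Numerical choices and degenerate inputs

* All coordinates are 0-based half-open; strand "." is treated as "+" with
  a warning; RepeatMasker `.out` rows are shifted from 1-based inclusive.
* A cut exactly on an element's end coordinate is outside it (half-open
  containment); boundary behaviour is pinned by tests.
* `D` comparisons and alignment tie-breaks use a 1e-12 tolerance; alignment
  ties prefer forward orientation, then smaller |offset|, then the negative
  offset.
* MEME output prints 6 decimals with per-column rounding residuals absorbed
  into the largest entry, so written libraries re-read to columns summing
  to 1 exactly and round-trip byte-identically.
* Zero-total expression columns, empty intact sets, empty intervals,
  even smoothing windows, non-stochastic PWM columns, and degenerate t-test
  groups raise immediate errors naming the offender.
* Permutation sub-seeds derive from query sequence content, so match
  p-values are independent of scan order and exactly strand-symmetric.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
150-kb reference genome (≈ 18,000 insertions × 4 stages), 100 random
profiles for the caller-vs-oracle check, 50 random PWM pairs for the
aligner-vs-brute-force check, and 200 permutation calibration trials at
`n_perm = 999`; the whole suite completes in well under a minute on one
core, and the end-to-end run in a few seconds. These sizes were chosen so
that every stochastic check has comfortable statistical resolution while
remaining desk-scale.

## Known limitations

* Intactness is checked on raw annotation records; fragmented RepeatMasker
  hits of one insertion are not merged first (the original procedure is
  silent on this).
* The footprint caller's defaults were tuned on the synthetic conditions;
  real profiles with strong Tn5 sequence bias may need wider smoothing or
  bias-corrected input.
* The permutation E-value is calibrated but not byte-compatible with
  Tomtom's analytic null; thresholds transfer in spirit, not numerically.
* The published footprint coordinates are hand-curated and unpublished, so
  they cannot serve as a test surface; recovery is validated against
  planted ground truth instead.
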