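---
title: "Calling and classifying switch-junction repair patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and classifying switch-junction repair patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchjxn)
```

## The problem

Class-switch recombination (CSR) joins a broken donor switch region (Sμ) to
an acceptor switch region (Sα, Sγ) of the immunoglobulin heavy-chain locus.
The joining pathway leaves a footprint in the junction sequence: classical
non-homologous end joining (c-NHEJ) tends to produce blunt joins and small
untemplated insertions, while alternative end joining (a-NHEJ) anneals the
two ends at perfectly matched microhomology and resects further. Given
Sanger-length junction amplicons and the two reference sequences, the
analysis problem is (i) to locate the breakpoint in each read, (ii) to
measure the junction's microhomology or insertion, (iii) to classify each
junction into the standard four categories — direct joins, small
insertions, 1–6 bp microhomology, ≥ 7 bp microhomology — and (iv) to test
whether two cohorts differ per category. The same machinery applies to
repair junctions of an integrated DSB reporter, where the readout is the
deletion size, insertion content and microhomology usage relative to the
reconstructed cut.

## Breakpoint model

A junction read is modelled as

    donor flank  +  (untemplated insertion | nothing)  +  acceptor flank

Each flank is aligned *semi-globally*: every base of the flank must be
explained, but both ends of the reference are free — the amplicon starts
somewhere inside the S region, and the junction side is exactly what we
want to locate. Alignment uses affine gaps: a gap of length $g$ costs
`gap_open` + $g\,\cdot$ `gap_extend`. Insertion bases between the two flank
alignments are left unaligned and score 0, which yields the natural
operational definition of an untemplated insertion: a junction base is
absorbed into a flank only when it extends that flank by a matching base
(+1), stays an insertion when it matches neither reference (0 beats the
mismatch penalty), and never splits the difference.

The caller computes, with a dynamic program in C++, the best semi-global
score of every read prefix against the donor and of every read suffix
against the acceptor, then maximizes the sum over all splits
(prefix, insertion, suffix). This is exact for the model above; the test
suite verifies it against an independent exhaustive enumeration over
(prefix length, insertion length, donor end, acceptor start) written in
plain R.

Microhomology is computed *post hoc* at the called coordinates as the
maximal perfectly matched extension on both sides of the junction. It is
deliberately not part of the alignment objective: the four-category scheme
is defined on perfectly matched homology, and the quantity is invariant to
which equivalent placement inside a homology window the caller reports.
`N` bases (Sanger ambiguity calls) score as mismatches in the alignment
and never match during microhomology extension, so ambiguous basecalls
cannot create phantom homology.

### Tie-breaking and determinism

Several splits can share the maximal score — always, in fact, when the
junction lies inside a homology window. Calls are made deterministic by a
total order: larger microhomology first (the category scheme is defined on
maximal homology), then the donor-maximal placement (largest donor end,
then largest acceptor start), then the shorter insertion. We use the
donor-maximal convention uniformly, for placements inside one homology
window and for the rare exact ties between distinct placements;
microhomology length, insertion length and all downstream classification
are unaffected by this choice.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `match` | +1 | per matched base |
| `mismatch` | −2 | per mismatched base; also for any `N` |
| `gap_open` | −4 | once per gap |
| `gap_extend` | −1 | per gapped base |
| `min_flank` | 15 nt | shortest admissible flank per side |
| `footprint_min_len` | 15 nt | shortest intermediate segment |
| `footprint_min_ident` | 0.90 | identity gate for the segment |

The scoring triple is a conventional Sanger-grade scheme (mismatches are
rare point errors; gaps rarer still). `min_flank` guards against spurious
splits in repeat-rich S regions: a read whose donor or acceptor flank
would be shorter than 15 nt, or whose best flank score is not positive on
both sides, is flagged *uncallable* and excluded from classification
rather than guessed at.

### Sequential-switching footprints

A junction may retain a block of an intermediate switch region (e.g.
Sμ–Sγ3–Sγ2 after two successive switch events). For each candidate
intermediate the caller takes the best local alignment of the read against
it and accepts a three-part segmentation when the segment spans ≥ 15 nt of
the read at ≥ 90% identity and the three-part total strictly exceeds the
two-part score. The thresholds are configurable; the defaults are strict
enough that unrelated repeat sequence does not trigger footprints in the
test constructions, and the strict-improvement rule means a footprint is
never reported when two segments explain the read equally well. Only the
single best local hit per intermediate is considered — a deliberate
simplification; deeply nested multi-intermediate footprints are out of
scope.

### Reporter mode

For an integrated cut reporter, `reporter[0, cut_left)` acts as donor and
`reporter[cut_right, end)` as acceptor; the junction is called exactly as
above and the deletion is
`(cut_left − donor_end) + (acceptor_start_global − cut_right)`, i.e. the
bases lost relative to perfect religation of the two nuclease sites.
Junction labels: `deletion` when the deletion is positive, otherwise
`insertion` when untemplated bases are present, otherwise `blunt`. Mixed
events (deletion *and* insertion) are labelled by their deletion, which
dominates the mutational-signature readout; microhomology usage is
reported among deletion-bearing junctions only.

## Classification and cohort statistics

Classification partitions callable junctions: insertions first (a junction
with an untemplated insertion *and* incidental flanking homology counts as
insertion — the published tables place small insertions under the 0 bp
homology column, and the categories must partition), then microhomology
0 / 1–6 / ≥ 7. Cohort percentages are integers rounded half away from
zero, which reproduces the published percentage rows; note that two cells
of the published Sμ–Sα table (34 of 82 printed as 42%, 50 of 213 printed
as 24%) do not match any standard rounding of their printed counts — we
compute 41% and 23% and do not chase the discrepancy.

Cohorts are compared per category with the uncorrected Pearson χ² on the
2×2 table (in-category vs rest). No continuity correction is applied:
only the uncorrected statistic reproduces the published p-values from the
published counts, as the test suite verifies in closed form. Categories
absent from both cohorts (e.g. ≥ 7 bp microhomology at Sμ–Sγ junctions)
produce a degenerate table and are reported as `NA` rather than 0 or 1.
No multiple-testing adjustment is applied by default, matching
per-category reporting; Holm adjustment is available by flag. The
Mann–Whitney U test uses the exact null distribution (doubled one-sided
tail, capped at 1) when $mn \le 400$ with no ties, and the tie-corrected
normal approximation without continuity correction otherwise — the
convention is fixed so results are reproducible, and the exact branch is
verified against full permutation enumeration.

## The synthetic-data generator

No raw patient reads accompany the published junction tables, so the
package ships a generator that emulates the study's sequencing material:

* **References** are tandem arrays of short motifs (the Sμ-like pentamers
  `GAGCT`/`GGGCT` by default) with per-base divergence 0.1 — repeat-rich,
  like real S regions, which is exactly what makes breakpoint calling
  non-trivial.
* **Reads** are a donor flank plus an acceptor flank (100–250 nt each,
  uniform, giving 200–500 nt reads as in Sanger-sequenced junction
  fragments), joined directly, through an untemplated insertion
  (length 1 + Geometric, mean 2.5 nt), or across a planted microhomology
  of sampled length.
* **Microhomology is planted, not hoped for**: a junction needing
  microhomology $k$ copies $k$ donor bases into the acceptor at the chosen
  breakpoint and pins the two flanking positions to differ, so the ground
  truth is realizable by construction. Planting edits go through a
  constraint engine that freezes every touched position; a later read may
  reuse frozen positions only compatibly, otherwise its coordinates are
  resampled. After all edits, the truth table is recomputed from the
  *final* references — every truth record is re-derivable from its read
  and the returned references, and the generator never lies even when a
  placement had to fall back.
* **Noise** is substitution-only by default at 0.002 per base, a
  placeholder for the unknown Sanger error rate of the original material
  (surfaced in the configuration); insertion/deletion noise is off by
  default so that truth-versus-call comparisons stay crisp.
* **Presets** `"control-like"` (16/24/36/24% across the four categories)
  and `"ICF2-like"` (5/13/42/40%) carry the published cohort spectra, with
  mass spread uniformly over lengths 1–6 and 7–12 within the two
  microhomology classes (the published table bins lengths, so the
  within-bin law is our choice).

In reporter mode, deletion sizes follow a shifted-geometric law
(`1 + Geom(1/mean)`, default mean 8 nt) split binomially between the two
sides. Deletion junctions carry planted microhomology like switch-mode
reads; `plant_mh = FALSE` disables planting so the deletion-size law is
sampled without constraint interaction — junction coordinates crowd
around the cut sites in reporter mode, and constraint resampling there
would slightly bias the size law, so distribution-law checks use the
unplanted mode while microhomology-usage checks use the planted one.
Deletions with zero microhomology arise only in unplanted mode; the
planted law has support on lengths ≥ 1.

What the generator does **not** emulate: AID hotspot targeting within the
repeats, chromatogram-level quality, PCR chimeras, and indel sequencing
errors (noise is substitution-only). Passing tests on
this material therefore certify the algorithmic pipeline — breakpoint
recovery, classification, statistics — under realistic repeat structure
and point noise, not the full error profile of wet-lab Sanger data.

## Verification strategy and problem sizes

The test suite runs five layers, scaled to desk-size:

1. **Exact reproduction**: the packaged junction-count table pushed
   through `cohort_table()`/`compare_categories()` must reproduce the
   published percentages and the three per-category χ² p-values to four
   decimals.
2. **Oracle equivalence**: on 500 random instances (reads ≤ 60 nt,
   references ≤ 80 nt), the caller's score and microhomology must equal an
   independent exhaustive enumeration in every case.
3. **Parameter recovery**: on 500 noise-free simulated junctions per
   preset (donor 3 kb, acceptor 6 kb — realistic S-region scale), the
   called class proportions must fall inside the 99% binomial interval of
   the configured masses, and with substitution noise 0.002 the
   microhomology length must be recovered exactly for ≥ 95% of reads.
4. **Regime discrimination**: across 100 replicate pairs of 200-read
   control-like vs ICF2-like cohorts, the ≥ 7 bp category must differ at
   p < 0.05 in at least 80 pairs. This power property concerns the
   sampling distribution of the per-category test under the preset
   spectra, so the replicates feed the generator's class outcomes directly
   into the summary and comparison stages; the caller's fidelity on these
   settings is certified separately by layer 3.
5. **Calibration**: under a common multinomial null (two 200-read cohorts
   from the same spectrum), the per-category test must reject at
   0.05 ± 0.02 over 1000 replicates.

`scripts/acceptance.R` re-runs all five layers from scratch under a
user-supplied seed.

## Known limitations

* Only perfectly matched microhomology is scored; mismatch-tolerant
  "imperfect homology" definitions are excluded by design.
* The caller assumes one junction per read (plus at most one intermediate
  segment); complex rearrangements with multiple templates are out of
  scope.
* Reads are assumed sense-strand; reverse-complement rescue is available
  (`try_revcomp`) but doubles runtime.
* The two published-table rounding anomalies and the published
  sequential-switching percentage (9% against 1 of 46 junctions) are
  inconsistencies of the source material; the package computes from
  counts and does not reproduce them.
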