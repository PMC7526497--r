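# switchjxn

Repair-pattern analysis of class-switch recombination (CSR) junctions.

During CSR, activation-induced deaminase (AID) creates double-strand breaks
in the repeat-rich switch (S) regions of the immunoglobulin heavy-chain
locus; the broken donor region (Sμ) is joined to an acceptor region (Sα or
Sγ). How the ends are joined leaves a sequence footprint: classical
non-homologous end joining (c-NHEJ) produces blunt joins and small
untemplated insertions, while alternative end joining (a-NHEJ) anneals the
ends at stretches of perfectly matched *microhomology* and produces larger
deletions. Comparing the spectrum of junction footprints between a patient
cohort and controls therefore reads out which repair pathway the patients'
B cells are using. `switchjxn` is for immunology and DNA-repair groups who
Sanger-sequence switch junctions (or repair junctions of an integrated
DSB reporter) and want a reproducible, tested route from reads to the
standard four-category repair-pattern table and its cohort statistics.

## What the package computes

**Breakpoint calling.** Each junction read is split into a donor prefix, an
optional untemplated insertion, and an acceptor suffix. Both flanks are
aligned semi-globally (free at the junction side and at the amplicon end)
with affine gaps, and the split maximizing the total alignment score is
selected; insertion bases at the junction are unaligned. For a called
junction with donor end *d* and acceptor start *a* (0-based, half-open),
the microhomology is the perfectly matched homology spanning the junction,

    mh = max{ l : donor[d-l, d) = acceptor[a-l, a) }
       + max{ r : donor[d, d+r) = acceptor[a, a+r) },

with `N` never matching. A three-part segmentation through an intermediate
S region (e.g. Sμ–Sγ3–Sγ2) is reported as a *sequential-switching
footprint* when it strictly beats the two-part score.

**Classification.** Junctions partition into four categories: `direct`
(blunt, mh = 0), `insertion` (untemplated bases), `mh_1_6` (1–6 bp) and
`mh_ge7` (≥ 7 bp). Cohort tables carry counts and integer percentages
(rounded half away from zero).

**Cohort statistics.** Per category, the two cohorts are compared with the
uncorrected Pearson χ² test on the 2×2 table (in-category vs rest):
χ² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d)), df = 1. A Mann–Whitney U test
(exact for small untied samples) is provided for junction characteristics,
plus the scalar assay formulas for plasmid-integration NHEJ efficiency and
relative protein accumulation in laser tracks.

**Synthetic data.** A generator emulates repeat-rich S-region references
and junction formation under configurable regimes with full ground truth —
including the `"control-like"` and `"ICF2-like"` presets carrying the
published class spectra — for both switch-region and cut-reporter modes.

## Worked example

Feed the published Sμ–Sα junction counts (ICF2 patients vs healthy
children) through the summary and comparison stages:

```r
library(switchjxn)
icf2 <- cohort_table(c(4, 11, 34, 33), "ICF2")      # direct, insertion, 1-6, >=7
ctrl <- cohort_table(c(34, 52, 77, 50), "controls")
icf2
#>   cohort class     count percent total
#> 1 ICF2   direct        4       5    82
#> 2 ICF2   insertion    11      13    82
#> 3 ICF2   mh_1_6       34      41    82
#> 4 ICF2   mh_ge7       33      40    82
compare_categories(icf2, ctrl)
#>   class     count_a total_a count_b total_b prop_a prop_b direction statistic p_value
#> 1 direct          4      82      34     213 0.0488  0.160 down          6.48  0.0109
#> 2 insertion      11      82      52     213 0.134   0.244 down          4.26  0.0389
#> 3 mh_1_6         34      82      77     213 0.415   0.362 up            0.712 0.399
#> 4 mh_ge7         33      82      50     213 0.402   0.235 up            8.23  0.00411
```

The patients show significantly less direct end-joining (5% vs 16%,
p = 0.0109), fewer insertions (13% vs 24%, p = 0.0389) and more long
microhomology (40% vs 24%, p = 0.0041) — the a-NHEJ shift. `autoplot()`
on either object draws the corresponding figure.

The same machinery runs end to end on synthetic data:

```r
donor    <- make_switch_reference(3000, c("GAGCT", "GGGCT"), 0.1, seed = 11,
                                  name = "Smu", role = "donor")
acceptor <- make_switch_reference(6000, c("TGGGG", "TGAGC"), 0.1, seed = 12,
                                  name = "Salpha", role = "acceptor")
sim   <- simulate_junctions(donor, acceptor,
                            sim_preset("ICF2-like", n_reads = 100, seed = 13),
                            cohort = "ICF2")
calls <- call_junctions(sim$reads, sim$donor, sim$acceptor)
summarize_cohort(classify_calls(calls), "ICF2")
#>   cohort class     count percent total
#> 1 ICF2   direct        4       4   100
#> 2 ICF2   insertion    15      15   100
#> 3 ICF2   mh_1_6       42      42   100
#> 4 ICF2   mh_ge7       39      39   100
```

The recovered spectrum matches the configured ICF2-like masses
(5/13/42/40%) up to multinomial sampling; `sim$truth` carries the per-read
ground truth for direct validation. A thin command-line wrapper over these
functions is installed at `inst/scripts/switchjxn`
(`simulate`, `call`, `classify`, `summarize`, `compare`).

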