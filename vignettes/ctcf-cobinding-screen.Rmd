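---
title: "Screening CTCF co-binding and loop-promoting factors"
author: "ctcfscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening CTCF co-binding and loop-promoting factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcfscreen)
```

## The problem

CTCF anchors the majority of chromatin loops in mammalian genomes, and
cohesin stabilizes them, but many other chromatin proteins co-occupy
CTCF sites and may promote or modulate looping. Identifying such
factors computationally requires combining two kinds of evidence:
*co-localization* (does the factor's ChIP-seq peak set coincide with
CTCF binding sites more than expected?) and *loop association* (are
CTCF loops anchored at factor-co-bound sites stronger, and does factor
binding strength track loop strength?). `ctcfscreen` implements this
screen as a pipeline over the standard file formats of the field —
narrowPeak peaks, BEDPE loops with PET (paired-end tag) counts, BED
chromatin-state segmentations and TSS/enhancer tracks — with every
stage validated against planted ground truth on synthetic data.

All coordinates are 0-based half-open (BED native) on disk and in
memory; overlap and merge semantics follow `bedtools intersect` and
`bedtools merge` defaults (at least one shared base; bookended
intervals merge at distance 0). Internally, overlaps are computed with
per-chromosome `IRanges::findOverlaps`.

## Conserved CTCF reference sites

ChIA-PET peak sets give CTCF sites with direct evidence of loop
engagement. Peaks are first resized to 500 bp around their summits
(`resize_to_summit()`; chromosome boundaries clip rather than discard,
preserving telomere-proximal peaks, and odd widths place the extra base
on the right). `conserved_chiapet_peaks()` then keeps the peaks of a
designated reference cell type — the first set by default, for
reproducibility — that are supported by overlap in other cell types.
What "conserved across cell types" means is genuinely open; we default
to *all* cell types because the construction aims at near-universal
sites, and expose `min_cell_types` for weaker notions.
`hsc_sites()` adds the second, independent axis of evidence: support in
a large CTCF ChIP-seq compendium, with `min_datasets` again defaulting
to all. Both filters are monotone (raising a threshold can only shrink
the output), and the compendium support histogram
(`conservation_histogram()`) summarizes the conservation distribution.

## The overlap-ratio screen

For one factor dataset against a reference site set, `overlap_ratio()`
computes

    ratio = (reference sites overlapping >= 1 retained factor peak)
            / (total reference sites).

Factor peaks are sorted by their narrowPeak signal (column 7)
descending and truncated to the top 100,000 before resizing both sides
to 200 bp. The cap guards against very deep, noisy peak lists inflating
the ratio; the sort key is binding strength because "top peaks" in this
context means strongest peaks, with genomic position as a deterministic
tie-break. `rank_factors()` aggregates per-factor datasets by the
maximum ratio — a factor observed strongly in any one cell type counts
— and `ratio_scaling()` compares conserved-site ratios against
top-K genome-wide ratios (K in 30,000–60,000 or all) with per-K least
squares and Pearson correlations; a degenerate (zero-variance) axis is
reported as r = 0 with an explicit flag rather than `NA`, so downstream
tabulation never propagates missing values.

## Candidate regulatory modules

`build_crms()` resizes every peak of every factor to a common width
(100 bp by default — larger widths make nearby modules fuse; the 100 bp
choice keeps the merged regions compact) and merges them. Every input
peak lands in exactly one CRM, and each CRM records its member factors.
`select_ctcf_crms()` keeps CRMs containing exactly one CTCF peak —
regions with two or more CTCF sites are ambiguous for anchor-level
statistics — optionally also requiring cohesin and ChIA-PET support.
`width_percentile_interval()` reports the symmetric percentile interval
(default the central 90%) of CRM widths, the statistic used to choose
the 100 bp resize.

`cluster_crms()` clusters the binary CRM-by-factor co-binding matrix
with Ward linkage (`ward.D2`) on Euclidean distances and cuts the tree
at k = 4. The linkage and metric are a design choice — the consumer of
the clustering is only the four-level ordering — and the binary matrix
is used rather than signal values because membership is what the
co-binding density groups encode. Clusters are relabeled *dense* >
*medium* > *light* > *ctcf_solo* by descending mean co-binding count,
making labels stable across runs; *CTCF-solo* is operationalized as the
lowest-co-binding cluster rather than a hard zero-count rule. Inputs
with fewer distinct co-binding profiles than k raise an error rather
than silently returning degenerate clusters. `compare_groups()` runs
two-sided Wilcoxon rank-sum tests between all group pairs on any
per-CRM value (CTCF signal, anchor loop strength), skipping empty
groups with a warning.

## Anchor-level loop statistics

`assign_unique_ctcf()` retains loop anchors overlapping exactly one
CTCF peak; anchors with none or several are dropped (and counted), so
each retained anchor corresponds to a unique CTCF site.
`anchor_loop_strength()` sums PET counts over all loops mediated by an
anchor; a self-looping anchor contributes its count once per end. The
conservation law — total anchor strength equals the sum over loops of
PET count times the number of retained ends — holds exactly and is
asserted in the test suite.

`cobinding_strength_test()` partitions anchors by whether their 200
bp-resized CTCF peak region overlaps a factor peak (the same resizing
convention as the screen) and applies a *one-sided* Wilcoxon rank-sum
test (co-bound greater), because the screened hypothesis is
directional: co-binding promotes looping. A two-sided variant is
available via `alternative`. P-values are Bonferroni-adjusted for the
number of factors screened; following the source convention the
adjusted value is called "FDR" although it is a family-wise bound, and
the screen keeps factors with `-log10(FDR) >= 20`. A factor with an
empty stratum is marked untestable and excluded rather than forced
through the test.

`normalize_binding()` converts a peak-region read count to
`log2(count * 1e9 / (length * 1e6))`; a zero count takes a +1
pseudocount, consistent with the +1 used in loop fold changes. The
formula's precedence is read as `(count * 1e9) / (length * 1e6)`; any
alternative reading shifts all values by a constant and leaves Pearson
correlations — the consumed quantity — unchanged.

`state_category()` collapses 18-state chromatin labels onto five
categories (Tss-type states to promoter, Enh-type to enhancer, Tx/TxWk
to transcription, ReprPCWk to itself, everything else to quiescent) and
assigns each site the category with maximal base overlap, breaking ties
by the priority promoter > enhancer > transcription > reprPCWk > quies.
`stratified_correlation()` then computes, per category, the Pearson
correlation between normalized binding and log2 loop strength (+1 on
zero strengths), reporting `-log10` of the Bonferroni-adjusted p-value
— forced to exactly 0 (never `NaN` or negative zero) when the stratum
is unreliable: fewer than 1000 sites or raw p above 0.01.

`differential_loops()` applies the two-condition rule verbatim: drop
loops whose maximum count is below 2, compute
`fc = (control + 1) / (knockdown + 1)`, and call a loop differential
when the change exceeds 2-fold strictly in either direction, recording
the direction. Swapping the condition columns swaps directions but
preserves the differential set. `strength_change_by_binding_change()`
bins anchors by CTCF-binding log2 fold change (default edges at
±2-fold and ±1.2-fold, i.e. ±1 and ±0.263 on the log2 scale, intervals
closed on the right — only measure-zero boundary points depend on the
closure convention) and compares loop-strength fold-change
distributions between bins.

## Factor pairs at paired loop anchors

`pair_scores()` forms, for every loop, the cross product of the factor
sets bound at its two anchors; each ordered occurrence contributes the
loop's strength to the canonical unordered pair. Cross-product counting
was chosen over deduplicated counting because it makes the conservation
law exact — the total edge score equals the sum over loops of
`strength * |A| * |B|` — and renders the result independent of which
anchor is labeled first. Self-pairs are kept: the homotypic CTCF-CTCF
edge is real signal. `export_network()` writes a deterministic,
Cytoscape-loadable edge list.

## Enhancer-promoter loops and the five-way classification

`candidate_promoters()` takes ±500 bp around each TSS (one region per
transcript, unmerged); `active_elements()` keeps candidates
intersecting transcribed intervals (e.g. GRO-seq transcripts). A loop
qualifies as an EP loop when one anchor hits an active enhancer and the
*other* hits an active promoter — a single anchor containing both
element types does not qualify by itself, since a loop should connect
the two element classes; `extract_ep_loops()` expands each qualifying
loop over all (enhancer, promoter) combinations, in both orientations,
reflecting the multi-element content of 10 kb anchors. Loops called at
finer anchor resolution (e.g. 500 bp ChIA-PET anchors) are widened to
10 kb around their anchor centers before annotation.

`classify_relation()` compares a CTCF loop with an EP loop on their
genomically oriented spans, in the fixed precedence order: **4** both
anchor pairs reciprocally overlap ("same loop"); **1** the EP span lies
inside the CTCF span; **2** the converse; **3** the spans overlap
without containment; **5** disjoint spans or different chromosomes.
Containment is *contained-and-not-equal*: two distinct loops with
identical spans but non-matching anchors fall to category 3. This
choice keeps the classification total and single-valued and makes the
role-exchange symmetry exact — swapping the two loops maps 1 to 2 and 2
to 1 while fixing 3, 4 and 5 — which the test suite asserts on 10,000
random pairs. `relation_table()`/`relation_summary()` tabulate all
pairs; a loop may participate in several categories across its
pairings.

## The synthetic-data generator

`sim_config()` bundles every tunable. The defaults are the package's
study conditions:

| parameter | default | meaning |
|---|---|---|
| `genome` | 2 × 10 Mb | two chromosomes |
| `n_ctcf` | 2000 | master CTCF sites |
| `n_cell_types` | 4 | compendium cell types |
| `conservation_prob` | 0.9 | per-cell-type site presence |
| `signal_meanlog`, `signal_sdlog` | 3, 0.5 | lognormal peak signal |
| `conservation_signal_coupling` | 1 | logit-scale signal-presence coupling |
| factor panel | f ∈ {0.05, 0.2, 0.4, 0.6, 0.8, 0.95} | planted co-binding fractions, 500 background peaks each |
| `loop_spec` | 2000 loops, 500 bp anchors, PET ~ 1 + Poisson(4), boost 2 on the f = 0.2 factor | loop generator |
| `diff_spec` | 10% at fold 8 | planted condition effects |
| `ep_spec` | 400 TSS, 400 enhancers, 50% active | element tracks |

Master sites are placed one per slot on a per-chromosome grid with a
600 bp margin, guaranteeing at least 1.2 kb between summits: anchors
stay unambiguous (the unique-CTCF filter rarely fires on crowding) and
planted fractions are uncontaminated by chance overlaps. Factor peaks
are planted within ±50 bp of distinct CTCF summits; background peaks
are rejection-sampled at least 700 bp from any CTCF summit so that,
after 200 bp resizing, a background peak can never touch a reference
site — the planted fraction `f` is therefore the *exact* expected
overlap ratio. Conservation-signal coupling acts on the logit scale
(`plogis(qlogis(p) + coupling * z)` for a site with signal z-score z);
at coupling 0 presence is exactly Binomial, which the binomial
recovery tests rely on.

Loop PET counts follow 1 + Poisson(λ), multiplied by `loop_boost` once
per promoting factor bound at either anchor. The default promoting
factor is the f = 0.2 panel member: boosting propagates to a
"non-co-bound" anchor whenever its *partner* anchor is bound, so a
highly prevalent promoting factor would dilute the anchor-level
contrast the Wilcoxon screen measures; a selective binder both matches
the biology of specific loop regulators (which co-occupy only a
minority of CTCF sites) and keeps the planted effect identifiable.
Two-condition counts are independent Poisson draws; planted
differential loops shift the knockdown mean by the configured fold,
half decreased and half increased, exercising the direction symmetry
of the calling rule.

Elements (TSS and enhancers) occupy disjoint slots so candidate
promoters and enhancers never collide, and the active-transcription
interval of an active element is strictly contained in it — the
truth table therefore predicts `active_elements()` output exactly.
The chromatin-state segmentation tiles each chromosome gaplessly with
quiescent-heavy state frequencies.

Determinism: a single root seed drives one sub-stream per output (a
fixed polynomial hash of the seed and a stream label, kept below
2^31), so adding an output never perturbs existing ones, and identical
configurations produce byte-identical files (`write_simulation()`).

### What the generator does and does not emulate

It reproduces the *statistical* structure the pipeline consumes:
multi-cell-type conservation with signal coupling, planted co-binding
fractions, PET-count laws with factor-dependent boosts, condition fold
changes, element activity. It does not emulate motif sequence content,
read-level noise, peak-caller artifacts, chromatin-domain structure, or
the correlated occupancy of real co-factor families. Passing tests
therefore demonstrate that the statistics measure what they claim to
measure under known truth — not that any particular biological claim
holds in real data.

## Numerical choices and problem sizes

Tolerances on stochastic checks are three standard errors of the
estimated quantity (binomial SEs for proportions, the large-sample SE
`(1 - r^2)/sqrt(n - 3)` for Pearson r). Validation uses 2000 CTCF
sites, 2000 loops and 1000 random oracle instances per interval
operation at n ≤ 200 on 100 kb chromosomes — sizes at which binomial
tolerances are tight enough to detect implementation errors while the
whole suite runs in minutes on a single core. Wilcoxon tests use the
normal approximation (`exact = FALSE`) throughout, matching standard
practice at these sample sizes.

## Known limitations

* The conserved-site construction depends on which cell type is the
  reference; only the reference set's intervals are reported.
* The "FDR" of the co-binding screen is a Bonferroni (family-wise)
  adjustment, kept under that name for continuity with the screen's
  convention.
* Replicate handling is the caller's choice; `select_max_peaks()`
  implements the max-peak-count selector but nothing forces it.
* `classify_relation()` treats inter-chromosomal loops as category 5
  by definition.
* The generator's background peaks avoid CTCF sites entirely; real
  background exhibits weak, nonzero co-occupancy, so real overlap
  ratios carry a small positive bias the synthetic ratios do not.
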