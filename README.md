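# ctcfscreen

Screening CTCF co-binding factors and loop-promoting factors from peak
and loop data.

CTCF is the principal anchor protein of chromatin loops, but it does not
act alone: cohesin and a growing list of co-factors bind the same sites
and modulate loop formation. `ctcfscreen` implements, as a tested and
reusable R pipeline, the computational screen that identifies such
factors from standard epigenomics inputs — ChIP-seq peak sets
(narrowPeak), ChIA-PET/HiChIP loops (BEDPE with PET counts), chromatin
state segmentations (BED) and TSS/enhancer tracks — and validates every
stage end-to-end on synthetic data with planted ground truth.

## What the pipeline computes

1. **Conserved CTCF reference sites.** ChIA-PET peak sets from several
   cell types are resized to 500 bp around their summits; peaks
   supported in every cell type and backed by a CTCF ChIP-seq
   compendium become the "super conserved" reference set
   (`conserved_chiapet_peaks()`, `hsc_sites()`).
2. **Overlap-ratio screen.** For each factor dataset, peaks are sorted
   by signal, truncated to the top 100,000, resized to 200 bp, and the
   ratio `overlapped reference sites / total reference sites` is
   computed; factors are ranked by their maximum ratio
   (`overlap_ratio()`, `rank_factors()`, `ratio_scaling()`).
3. **Candidate regulatory modules (CRMs).** All factor peaks are resized
   to 100 bp and merged; CRMs containing exactly one CTCF peak are kept
   and hierarchically clustered (Ward on binary co-binding profiles)
   into *dense*, *medium*, *light* and *CTCF-solo* groups, compared by
   Wilcoxon rank-sum tests on CTCF signal and loop strength
   (`build_crms()`, `cluster_crms()`, `compare_groups()`).
4. **Anchor-level loop statistics.** Loop anchors with a unique CTCF
   peak get a loop strength — the sum of PET counts over all loops they
   mediate. Factors are screened by a one-sided Wilcoxon test of
   co-bound vs non-co-bound anchor strengths with Bonferroni adjustment
   and a `-log10(FDR) >= 20` gate; binding-strength/loop-strength
   Pearson correlations are computed per chromatin-state category with
   a reliability gate (n >= 1000 and p <= 0.01)
   (`assign_unique_ctcf()`, `anchor_loop_strength()`,
   `cobinding_strength_test()`, `stratified_correlation()`).
5. **Factor-pair networks.** Every factor pair across the two anchors
   of each loop is scored with the loop's strength and summed into a
   Cytoscape-loadable weighted network (`pair_scores()`,
   `export_network()`).
6. **Differential loops.** Between two conditions, loops with
   `max(count) < 2` are removed and the fold change
   `(control + 1) / (knockdown + 1)` calls loops differential when it
   exceeds 2-fold in either direction (`differential_loops()`).
7. **Enhancer-promoter loop classification.** Active promoters
   (TSS ± 500 bp intersecting transcribed regions) and enhancers define
   EP loops, expanded over all element combinations per 10 kb anchor;
   each CTCF loop/EP loop pair falls into exactly one of five positional
   categories — contains (1), contained (2), intersecting (3),
   same (4), separate (5) (`extract_ep_loops()`, `classify_relation()`).

The synthetic-data module (`sim_config()`, `simulate_all()`,
`write_simulation()`) generates all of these inputs with planted,
parameterized structure — co-binding fractions, loop-strength boosts,
condition fold changes, active-element fractions — so every statistic
above can be checked against known truth.

## Worked example

```r
library(ctcfscreen)

cfg <- sim_config(seed = 42)       # the default study conditions
sim <- simulate_all(cfg)
comp <- sim$compendium

# overlap-ratio screen against the master CTCF reference
recs <- do.call(rbind, lapply(sim$factors, overlap_ratio,
                              reference = comp$master, sizes = cfg$genome))
rank_factors(recs)[, c("factor", "max_ratio", "n_datasets")]
#>   factor max_ratio n_datasets
#> 1    F95      0.95          1
#> 2    F80      0.80          1
#> 3    F60      0.60          1
#> 4    F40      0.40          1
#> 5    F20      0.20          1
#> 6    F05      0.05          1

# anchor loop strengths and the loop-promoting screen
anchors <- unique(data.frame(chrom = c(sim$loops$chrom1, sim$loops$chrom2),
                             start = c(sim$loops$start1, sim$loops$start2),
                             end   = c(sim$loops$end1,   sim$loops$end2)))
ar <- assign_unique_ctcf(anchors, comp$cell_types[[1]])
#> assign_unique_ctcf: retained 1496 anchors; dropped 255 with no CTCF peak,
#> 0 with multiple
ar <- anchor_loop_strength(ar, sim$loops)
cobinding_strength_test(ar, sim$factors$F20,
                        n_factors_tested = length(sim$factors),
                        sizes = cfg$genome)[
  , c("factor", "n_cobound", "n_noncobound", "neg_log10_fdr", "passes_screen")]
#>   factor n_cobound n_noncobound neg_log10_fdr passes_screen
#> 1    F20       308         1188      23.74184          TRUE

# two-condition differential loop calling
dl <- differential_loops(sim$loops_conditions)
sum(dl$differential)                                  # 471 of 1953 loops
mean(dl$differential[dl$diff_planted])                # 0.953 planted recall
```

The planted co-binding fractions are recovered exactly as overlap
ratios; the factor whose binding was planted to double loop PET counts
(F20) clears the `-log10(FDR) >= 20` screen gate; and 95% of loops with
a planted 8-fold condition effect are called differential.

## Vignette

`vignettes/ctcf-cobinding-screen.Rmd` describes the statistical model
behind each stage, the synthetic-data generator and what it does and
does not emulate, all tunable parameters with their defaults, and the
package's design decisions and limitations.
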