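## Anchor-level loop-strength statistics: the unique-CTCF anchor table,
## the co-binding Wilcoxon screen, chromatin-state-stratified Pearson
## correlations and two-condition differential loop calling.

#' Assign a unique CTCF peak to each loop anchor
#'
#' Anchors overlapping exactly one CTCF peak are retained with that peak
#' attached; anchors with zero or two-plus CTCF peaks are dropped, which
#' ensures each retained loop anchor corresponds to a unique CTCF binding
#' site. Drop counts are reported via `message()` and as attributes.
#'
#' @param anchors interval data.frame of loop anchor regions.
#' @param ctcf CTCF [peak_set()].
#' @return Anchor data.frame with columns `ctcf_index`, `ctcf_start`,
#'   `ctcf_end`, `ctcf_summit`, `ctcf_signal`; attributes `n_dropped_zero`
#'   and `n_dropped_multi`.
#' @export
assign_unique_ctcf <- function(anchors, ctcf) {
  .check_intervals(anchors, "anchors")
  .check_intervals(ctcf, "ctcf peaks")
  if (!nrow(anchors)) {
    return(structure(anchors, n_dropped_zero = 0L, n_dropped_multi = 0L))
  }
  hits <- .find_ov(anchors, ctcf)
  cnt <- tabulate(hits$query, nbins = nrow(anchors))
  keep <- cnt == 1L
  idx <- rep(NA_integer_, nrow(anchors))
  one <- hits$query %in% which(keep)
  idx[hits$query[one]] <- hits$subject[one]
  out <- anchors[keep, , drop = FALSE]
  out$ctcf_index <- idx[keep]
  out$ctcf_start <- ctcf$start[out$ctcf_index]
  out$ctcf_end <- ctcf$end[out$ctcf_index]
  out$ctcf_summit <- ctcf$summit[out$ctcf_index]
  out$ctcf_signal <- ctcf$signal[out$ctcf_index]
  rownames(out) <- NULL
  n0 <- sum(cnt == 0L); n2 <- sum(cnt >= 2L)
  message(sprintf("assign_unique_ctcf: retained %d anchors; dropped %d with no CTCF peak, %d with multiple",
                  nrow(out), n0, n2))
  structure(out, n_dropped_zero = n0, n_dropped_multi = n2)
}

#' Anchor-level CTCF loop strength
#'
#' Loop strength of an anchor is the sum of PET tag counts over all loops
#' mediated by it: every loop end overlapping the anchor contributes the
#' loop's PET count (a self-looping anchor whose two ends both overlap it
#' contributes its count once per end).
#'
#' @param anchor_records anchor data.frame (e.g. [assign_unique_ctcf()]).
#' @param loops a [loop_set()].
#' @param pet column of `loops` holding the counts (default `pet_count`).
#' @return `anchor_records` with a `loop_strength` column.
#' @export
anchor_loop_strength <- function(anchor_records, loops, pet = "pet_count") {
  .check_intervals(anchor_records, "anchors")
  n <- nrow(anchor_records)
  anchor_records$loop_strength <- rep(0, n)
  if (!n || !nrow(loops)) return(anchor_records)
  ends <- data.frame(
    chrom = c(loops$chrom1, loops$chrom2),
    start = c(loops$start1, loops$start2),
    end = c(loops$end1, loops$end2))
  pets <- rep(as.numeric(loops[[pet]]), 2L)
  hits <- .find_ov(anchor_records, ends)
  qh <- hits$query
  if (length(qh)) {
    add <- tapply(pets[hits$subject], qh, sum)
    anchor_records$loop_strength[as.integer(names(add))] <- as.numeric(add)
  }
  anchor_records
}

#' Wilcoxon co-binding loop-strength screen for one factor
#'
#' Partitions anchors by whether their (200 bp summit-resized) CTCF peak
#' region overlaps a factor peak, then tests whether co-bound anchors
#' mediate stronger loops with a one-sided Wilcoxon rank-sum test
#' (co-bound greater; set `alternative` for a two-sided variant). The
#' p-value is Bonferroni-adjusted for the number of factors screened
#' (reported as "fdr", following the screen's naming, though it is a
#' family-wise adjustment) and the screen gate keeps factors with
#' -log10(fdr) >= 20.
#'
#' @param anchor_records anchors with `ctcf_start`/`ctcf_end`/
#'   `ctcf_summit` and `loop_strength` columns.
#' @param factor_peaks the factor's [peak_set()].
#' @param n_factors_tested number of factors in the screen (Bonferroni
#'   multiplier).
#' @param resize_width summit-window width applied to both the CTCF peak
#'   region and the factor peaks (bp).
#' @param sizes optional chromosome lengths.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param gate the -log10(fdr) screen threshold (default 20).
#' @return One-row data.frame: `factor`, `n_cobound`, `n_noncobound`,
#'   `statistic`, `p`, `fdr`, `neg_log10_fdr`, `passes_screen`,
#'   `testable`.
#' @export
cobinding_strength_test <- function(anchor_records, factor_peaks,
                                    n_factors_tested = 1L,
                                    resize_width = 200L, sizes = NULL,
                                    alternative = c("greater", "two.sided"),
                                    gate = 20) {
  alternative <- match.arg(alternative)
  stopifnot(!is.null(anchor_records$loop_strength))
  fname <- attr(factor_peaks, "factor") %||% "unknown"
  ctcf_regions <- data.frame(chrom = anchor_records$chrom,
                             start = anchor_records$ctcf_start,
                             end = anchor_records$ctcf_end,
                             summit = anchor_records$ctcf_summit)
  ctcf_regions <- resize_to_summit(ctcf_regions, resize_width, sizes)
  fp <- resize_to_summit(as.data.frame(factor_peaks), resize_width, sizes)
  cobound <- if (nrow(fp)) {
    .count_ov(ctcf_regions, fp) > 0L
  } else rep(FALSE, nrow(anchor_records))
  x <- anchor_records$loop_strength[cobound]
  y <- anchor_records$loop_strength[!cobound]
  if (!length(x) || !length(y)) {
    return(data.frame(factor = fname, n_cobound = length(x),
                      n_noncobound = length(y), statistic = NA_real_,
                      p = NA_real_, fdr = NA_real_,
                      neg_log10_fdr = NA_real_, passes_screen = FALSE,
                      testable = FALSE, stringsAsFactors = FALSE))
  }
  wt <- wilcox.test(x, y, alternative = alternative, exact = FALSE)
  fdr <- min(1, wt$p.value * n_factors_tested)
  data.frame(factor = fname, n_cobound = length(x),
             n_noncobound = length(y), statistic = unname(wt$statistic),
             p = wt$p.value, fdr = fdr, neg_log10_fdr = -log10(fdr),
             passes_screen = is.finite(fdr) && -log10(fdr) >= gate,
             testable = TRUE, stringsAsFactors = FALSE)
}

#' Length-normalized binding strength
#'
#' Normalizes a peak-region read count as
#' `log2((count * 1e9) / (length * 1e6))`, i.e. `log2(1000 * count /
#' length)`; zero counts take a +1 pseudocount before the log so the
#' transform stays finite.
#'
#' @param read_count non-negative read count(s).
#' @param region_length positive region length(s) in bp.
#' @return Numeric vector of normalized values.
#' @examples
#' normalize_binding(1, 1000)   # 0
#' normalize_binding(0, 500)    # 1
#' @export
normalize_binding <- function(read_count, region_length) {
  stopifnot(all(read_count >= 0), all(region_length > 0))
  log2(1000 * pmax(read_count, 1) / region_length)
}

.state_category_map <- c(
  TssA = "promoter", TssFlnk = "promoter", TssFlnkU = "promoter",
  TssFlnkD = "promoter", TssBiv = "promoter",
  EnhG1 = "enhancer", EnhG2 = "enhancer", EnhA1 = "enhancer",
  EnhA2 = "enhancer", EnhWk = "enhancer", EnhBiv = "enhancer",
  Tx = "transcription", TxWk = "transcription",
  ReprPCWk = "reprPCWk")

.category_levels <- c("promoter", "enhancer", "transcription",
                      "reprPCWk", "quies")

#' Collapse 18-state chromatin labels onto five categories
#'
#' Assigns each site the category (promoter, enhancer, transcription,
#' reprPCWk or quies) with maximal base overlap in a chromatin-state
#' segmentation; Tss-type states map to promoter, Enh-type to enhancer,
#' Tx/TxWk to transcription, ReprPCWk to reprPCWk and every other state
#' to quies. Ties go to the higher-priority category in the order
#' promoter > enhancer > transcription > reprPCWk > quies.
#'
#' @param sites interval data.frame.
#' @param segments state segmentation with a `name` column of state
#'   labels.
#' @return Character vector of categories, one per site (sites with no
#'   overlapping segment fall to `"quies"`).
#' @export
state_category <- function(sites, segments) {
  .check_intervals(sites, "sites")
  .check_intervals(segments, "segments")
  n <- nrow(sites)
  if (!n) return(character(0))
  cat_of_seg <- .state_category_map[segments$name]
  cat_of_seg[is.na(cat_of_seg)] <- "quies"
  hits <- .find_ov(sites, segments)
  qh <- hits$query; sh <- hits$subject
  ov <- pmin(sites$end[qh], segments$end[sh]) -
    pmax(sites$start[qh], segments$start[sh])
  ## accumulate overlap bases per (site, category)
  acc <- matrix(0, n, length(.category_levels),
                dimnames = list(NULL, .category_levels))
  ci <- match(cat_of_seg[sh], .category_levels)
  for (k in seq_along(.category_levels)) {
    sel <- ci == k
    if (any(sel)) {
      s <- tapply(ov[sel], qh[sel], sum)
      acc[as.integer(names(s)), k] <- as.numeric(s)
    }
  }
  ## max overlap; ties resolved by category priority (column order)
  best <- apply(acc, 1L, which.max)
  out <- .category_levels[best]
  out[rowSums(acc) == 0] <- "quies"
  out
}

#' Chromatin-state-stratified binding-loop correlation
#'
#' Within each of the five state categories, computes the Pearson
#' correlation between normalized factor binding and log2-transformed
#' loop strength (+1 pseudocount on zero strengths before the log). The
#' reported score is -log10 of the Bonferroni-adjusted p-value, forced to
#' exactly 0 whenever the stratum is unreliable: fewer than `min_n`
#' anchors or raw p > `p_gate`.
#'
#' @param binding numeric vector of normalized binding values.
#' @param loop_strength numeric vector of raw loop strengths.
#' @param category category label per anchor.
#' @param n_tests Bonferroni multiplier (default: number of categories
#'   present).
#' @param min_n reliability gate on stratum size (default 1000).
#' @param p_gate reliability gate on the raw p-value (default 0.01).
#' @return data.frame per category: `category`, `n`, `r`, `p`, `p_adj`,
#'   `reported_score`, `reliable`.
#' @export
stratified_correlation <- function(binding, loop_strength, category,
                                   n_tests = NULL, min_n = 1000L,
                                   p_gate = 0.01) {
  stopifnot(length(binding) == length(loop_strength),
            length(binding) == length(category))
  y_all <- log2(pmax(loop_strength, 1))
  cats <- intersect(.category_levels, unique(category))
  if (!length(cats)) cats <- unique(category)
  if (is.null(n_tests)) n_tests <- length(cats)
  out <- lapply(cats, function(cc) {
    sel <- which(category == cc & is.finite(binding) & is.finite(y_all))
    n <- length(sel)
    r <- NA_real_; p <- NA_real_
    if (n >= 3 && stats::sd(binding[sel]) > 0 && stats::sd(y_all[sel]) > 0) {
      ct <- cor.test(binding[sel], y_all[sel], method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    p_adj <- if (is.na(p)) NA_real_ else min(1, p * n_tests)
    reliable <- !is.na(p) && n >= min_n && p <= p_gate
    score <- if (reliable) -log10(p_adj) else 0
    if (!is.finite(score) || score < 0) score <- if (reliable) score else 0
    data.frame(category = cc, n = n, r = r, p = p, p_adj = p_adj,
               reported_score = score, reliable = reliable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Differential loop calling between two conditions
#'
#' The printed rule: loops whose maximum count over the two conditions is
#' below `min_max` are filtered out; the fold change is computed after
#' adding 1 to each count, `fc = (count_control + 1) / (count_kd + 1)`;
#' loops changing more than `fold_threshold`-fold in either direction are
#' differential.
#'
#' @param loops data.frame with `count_control` and `count_kd` columns.
#' @param min_max minimal maximum count to keep a loop (default 2).
#' @param fold_threshold fold-change threshold, strict (default 2).
#' @return The retained loops with columns `fold_change`, `differential`
#'   and `direction` (`"down_in_kd"` when the control count is higher,
#'   `"up_in_kd"` when the knockdown count is higher, `"stable"`
#'   otherwise); attribute `n_filtered` counts removed loops.
#' @examples
#' differential_loops(data.frame(count_control = c(3, 1, 4),
#'                               count_kd = c(0, 1, 2)))
#' @export
differential_loops <- function(loops, min_max = 2L, fold_threshold = 2) {
  stopifnot(all(c("count_control", "count_kd") %in% names(loops)))
  keep <- pmax(loops$count_control, loops$count_kd) >= min_max
  out <- loops[keep, , drop = FALSE]
  fc <- (out$count_control + 1) / (out$count_kd + 1)
  out$fold_change <- fc
  out$differential <- fc > fold_threshold | 1 / fc > fold_threshold
  out$direction <- ifelse(!out$differential, "stable",
                          ifelse(fc > fold_threshold, "down_in_kd", "up_in_kd"))
  rownames(out) <- NULL
  structure(out, n_filtered = sum(!keep))
}

#' Loop-strength change stratified by CTCF binding change
#'
#' Bins anchors by their CTCF binding log2 fold change (default bin edges
#' at +/- 2-fold and +/- 1.2-fold: -1, -0.263, 0.263, 1; intervals closed
#' on the right) and compares the distribution of loop-strength log2 fold
#' changes between bins with two-sided Wilcoxon rank-sum tests. If only
#' one bin is occupied, no tests are run and a warning is raised.
#'
#' @param binding_l2fc per-anchor CTCF binding log2 fold change.
#' @param strength_l2fc per-anchor loop-strength log2 fold change.
#' @param bin_edges inner bin edges on the log2 scale.
#' @return list with `bins` (per-bin `n` and `median_strength_l2fc`) and
#'   `tests` (pairwise Wilcoxon table as in [compare_groups()]).
#' @export
strength_change_by_binding_change <- function(binding_l2fc, strength_l2fc,
                                              bin_edges = c(-1, -0.263,
                                                            0.263, 1)) {
  stopifnot(length(binding_l2fc) == length(strength_l2fc))
  breaks <- c(-Inf, sort(bin_edges), Inf)
  bin <- cut(binding_l2fc, breaks = breaks, right = TRUE)
  occupied <- levels(bin)[tabulate(bin, nbins = nlevels(bin)) > 0]
  bins <- data.frame(
    bin = levels(bin),
    n = as.integer(tabulate(bin, nbins = nlevels(bin))),
    median_strength_l2fc = vapply(levels(bin), function(b) {
      v <- strength_l2fc[which(bin == b)]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  if (length(occupied) < 2L) {
    warning("only one occupied binding-change bin; no tests run",
            call. = FALSE)
    tests <- data.frame(group1 = character(0), group2 = character(0),
                        n1 = integer(0), n2 = integer(0),
                        statistic = numeric(0), p = numeric(0))
  } else {
    tests <- compare_groups(strength_l2fc, as.character(bin))
  }
  list(bins = bins, tests = tests)
}
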