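## Construction of super-conserved CTCF binding sites: loop-competent CTCF
## sites shared across ChIA-PET cell types and supported by a large
## ChIP-seq compendium.

#' Cross-cell-type conserved ChIA-PET peaks
#'
#' Starting from one 500 bp summit-resized ChIA-PET peak set per cell
#' type, returns the peaks of a designated reference cell type that are
#' supported by overlap in at least `min_cell_types - 1` of the other
#' sets. The default demands support in every cell type.
#'
#' @param peaksets list of [peak_set()]s (>= 2), one per cell type; peaks
#'   are expected to be pre-resized (see [resize_to_summit()]).
#' @param min_cell_types minimal number of cell types (including the
#'   reference) a peak must appear in; default all.
#' @param reference index of the reference set whose intervals are
#'   reported (default the first, for reproducibility).
#' @return A [peak_set()]: the supported reference peaks, with a column
#'   `n_chiapet_cell_types` giving the support count.
#' @export
conserved_chiapet_peaks <- function(peaksets,
                                    min_cell_types = length(peaksets),
                                    reference = 1L) {
  if (length(peaksets) < 2L) {
    stop("need at least 2 ChIA-PET peak sets", call. = FALSE)
  }
  if (min_cell_types > length(peaksets)) {
    stop("min_cell_types exceeds the number of peak sets", call. = FALSE)
  }
  ref <- peaksets[[reference]]
  others <- peaksets[-reference]
  support <- rep(1L, nrow(ref))
  if (nrow(ref)) {
    for (o in others) {
      if (nrow(o)) {
        support <- support + as.integer(.count_ov(ref, o) > 0L)
      }
    }
  }
  out <- ref[support >= min_cell_types, , drop = FALSE]
  out$n_chiapet_cell_types <- support[support >= min_cell_types]
  out
}

#' Super-conserved CTCF sites from a ChIP-seq compendium
#'
#' Filters conserved ChIA-PET peaks by support in a CTCF ChIP-seq
#' compendium: a site is kept when at least `min_datasets` compendium peak
#' sets overlap it. Each retained site is annotated with its dataset
#' support count (whose histogram is the conservation distribution) and
#' the mean signal of its supporting compendium peaks.
#'
#' @param conserved output of [conserved_chiapet_peaks()].
#' @param compendium non-empty list of [peak_set()]s.
#' @param min_datasets minimal supporting datasets, in
#'   `[1, length(compendium)]`; default all.
#' @return data.frame of conserved sites with `n_compendium_datasets` and
#'   `mean_signal` columns.
#' @export
hsc_sites <- function(conserved, compendium,
                      min_datasets = length(compendium)) {
  if (!length(compendium)) {
    stop("compendium must be a non-empty list of peak sets", call. = FALSE)
  }
  if (min_datasets < 1L || min_datasets > length(compendium)) {
    stop("min_datasets must be in [1, length(compendium)]", call. = FALSE)
  }
  .check_intervals(conserved, "conserved sites")
  n <- nrow(conserved)
  support <- rep(0L, n)
  sig_sum <- rep(0, n)
  sig_n <- rep(0L, n)
  if (n) {
    for (ps in compendium) {
      if (!nrow(ps)) next
      hits <- .find_ov(conserved, ps)
      qh <- hits$query
      support[unique(qh)] <- support[unique(qh)] + 1L
      if (!is.null(ps$signal) && length(qh)) {
        add <- tapply(ps$signal[hits$subject], qh, sum)
        idx <- as.integer(names(add))
        sig_sum[idx] <- sig_sum[idx] + as.numeric(add)
        sig_n <- sig_n + tabulate(qh, nbins = n)
      }
    }
  }
  keep <- support >= min_datasets
  out <- conserved[keep, , drop = FALSE]
  out$n_compendium_datasets <- support[keep]
  out$mean_signal <- ifelse(sig_n[keep] > 0, sig_sum[keep] / sig_n[keep], NA_real_)
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

#' Conservation histogram
#'
#' Distribution of compendium support counts over super-conserved sites:
#' how many sites are backed by exactly k compendium datasets.
#'
#' @param sites output of [hsc_sites()] (needs `n_compendium_datasets`).
#' @return Named integer vector mapping support count to number of sites;
#'   sums to `nrow(sites)`.
#' @export
conservation_histogram <- function(sites) {
  if (!nrow(sites)) return(setNames(integer(0), character(0)))
  tab <- table(sites$n_compendium_datasets)
  setNames(as.integer(tab), names(tab))
}
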