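## The overlap-ratio co-binding screen: what fraction of reference CTCF
## sites is co-bound by each factor's (top) peaks.

#' Overlap ratio of a factor against a CTCF reference
#'
#' The stringent-overlap convention: factor peaks are sorted by signal
#' descending (ties by genomic position, for determinism), truncated to
#' the top `cap` (at most the top 100,000 peaks are used, to avoid false
#' positives from noisy deep peak lists), both factor peaks and reference
#' sites are resized to `resize_width` around their summits, and the ratio
#' is the fraction of reference sites hit by at least one retained factor
#' peak.
#'
#' @param factor_set a [peak_set()].
#' @param reference non-empty data.frame of reference CTCF sites (with
#'   `summit`; resized internally).
#' @param cap maximal number of top factor peaks retained.
#' @param resize_width summit-window width for both sides (bp).
#' @param sizes optional chromosome lengths for boundary clipping.
#' @return One-row data.frame: `factor`, `dataset`, `cell_type`,
#'   `n_reference`, `n_overlapped`, `ratio` (= n_overlapped/n_reference).
#' @export
overlap_ratio <- function(factor_set, reference, cap = 100000L,
                          resize_width = 200L, sizes = NULL) {
  .check_intervals(reference, "reference")
  if (!nrow(reference)) stop("reference set is empty", call. = FALSE)
  .check_intervals(factor_set, "factor peaks")
  fp <- as.data.frame(factor_set)
  if (nrow(fp)) {
    ord <- order(-fp$signal, fp$chrom, fp$start)
    fp <- fp[head(ord, cap), , drop = FALSE]
    fp <- resize_to_summit(fp, resize_width, sizes)
  }
  ref <- resize_to_summit(as.data.frame(reference), resize_width, sizes)
  n_overlapped <- count_overlapping(ref, fp)
  data.frame(
    factor = attr(factor_set, "factor") %||% "unknown",
    dataset = attr(factor_set, "dataset") %||% "unknown",
    cell_type = attr(factor_set, "cell_type") %||% "unknown",
    n_reference = nrow(ref),
    n_overlapped = n_overlapped,
    ratio = n_overlapped / nrow(ref),
    stringsAsFactors = FALSE)
}

#' Rank factors by maximum overlap ratio
#'
#' One row per factor, ranked by the maximum ratio over that factor's
#' datasets (the per-dataset "dots" are retained as a list column); ties
#' broken lexicographically by factor name.
#'
#' @param records data.frame of [overlap_ratio()] rows.
#' @param top_n number of top factors returned (default 50).
#' @return data.frame `factor`, `max_ratio`, `n_datasets`, `ratios`
#'   (list column of named per-dataset ratios), ordered by rank.
#' @export
rank_factors <- function(records, top_n = 50L) {
  stopifnot(is.data.frame(records), all(c("factor", "ratio") %in% names(records)))
  if (!nrow(records)) {
    return(data.frame(factor = character(0), max_ratio = numeric(0),
                      n_datasets = integer(0)))
  }
  sp <- split(records, records$factor)
  out <- data.frame(
    factor = names(sp),
    max_ratio = vapply(sp, function(d) max(d$ratio), numeric(1)),
    n_datasets = vapply(sp, nrow, integer(1)),
    stringsAsFactors = FALSE)
  out$ratios <- lapply(sp, function(d) {
    setNames(d$ratio, if (!is.null(d$dataset)) d$dataset else NULL)
  })
  out <- out[order(-out$max_ratio, out$factor), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_n)
}

#' Compare conserved-site ratios against genome-wide top-K ratios
#'
#' Pairs each factor/dataset's overlap ratio computed on the conserved
#' (hscCTCF-style) reference with the ratio computed on a top-K
#' genome-wide CTCF reference, and summarizes each K by a least-squares
#' line and a Pearson correlation. A degenerate axis (zero variance) is
#' reported as r = 0 with `degenerate = TRUE`.
#'
#' @param records_hsc [overlap_ratio()] rows on the conserved reference.
#' @param records_topk named list of record data.frames, one per K (e.g.
#'   `list("30000" = ..., "all" = ...)`).
#' @return list with `scatter` (per-K paired ratios) and `fits` (per-K
#'   `slope`, `intercept`, `r`, `n`, `degenerate`).
#' @export
ratio_scaling <- function(records_hsc, records_topk) {
  stopifnot(is.data.frame(records_hsc), is.list(records_topk),
            !is.null(names(records_topk)))
  key <- function(d) paste(d$factor, d$dataset, sep = "\r")
  scatter <- list(); fits <- list()
  for (K in names(records_topk)) {
    rk <- records_topk[[K]]
    m <- match(key(records_hsc), key(rk))
    ok <- !is.na(m)
    x <- records_hsc$ratio[ok]
    y <- rk$ratio[m[ok]]
    scatter[[K]] <- data.frame(K = K, factor = records_hsc$factor[ok],
                               dataset = records_hsc$dataset[ok],
                               ratio_hsc = x, ratio_topk = y,
                               stringsAsFactors = FALSE)
    degenerate <- length(x) < 2 ||
      stats::var(x) == 0 || stats::var(y) == 0
    if (degenerate) {
      slope <- NA_real_; intercept <- NA_real_; r <- 0
    } else {
      fit <- stats::lm.fit(cbind(1, x), y)
      intercept <- unname(fit$coefficients[1])
      slope <- unname(fit$coefficients[2])
      r <- stats::cor(x, y)
    }
    fits[[K]] <- data.frame(K = K, slope = slope, intercept = intercept,
                            r = r, n = length(x), degenerate = degenerate,
                            stringsAsFactors = FALSE)
  }
  list(scatter = do.call(rbind, scatter), fits = do.call(rbind, fits))
}

#' Pick the replicate with the most peaks
#'
#' Helper replicate selector: among several datasets of the same factor,
#' keep the one with the maximum number of peaks.
#'
#' @param peaksets list of [peak_set()]s of one factor.
#' @return The selected [peak_set()].
#' @export
select_max_peaks <- function(peaksets) {
  stopifnot(length(peaksets) >= 1L)
  peaksets[[which.max(vapply(peaksets, nrow, integer(1)))]]
}
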