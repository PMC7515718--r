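#' Construct a peak set
#'
#' A peak set is one ChIP-seq (or ChIA-PET peak) dataset: a data.frame of
#' peaks in 0-based half-open coordinates carrying a summit offset and a
#' signal value (the narrowPeak column-7 enrichment), tagged with the factor
#' name, the cell type and a dataset identifier.
#'
#' @param peaks data.frame with at least `chrom`, `start`, `end`. Optional
#'   columns `name`, `score`, `strand`, `signal`, `pvalue`, `qvalue`,
#'   `summit` (offset from `start`; defaults to the interval midpoint) are
#'   filled in when absent. Extra columns are preserved.
#' @param factor factor (protein) name.
#' @param cell_type cell-type label.
#' @param dataset dataset identifier; defaults to `"<factor>.<cell_type>"`.
#' @return A `peak_set`: a data.frame with attributes `factor`, `cell_type`
#'   and `dataset`.
#' @examples
#' ps <- peak_set(data.frame(chrom = "chr1", start = 100, end = 500),
#'                factor = "CTCF", cell_type = "GM12878")
#' @export
peak_set <- function(peaks, factor = "unknown", cell_type = "unknown",
                     dataset = NULL) {
  .check_intervals(peaks, "peaks")
  n <- nrow(peaks)
  len <- peaks$end - peaks$start
  if (is.null(peaks$name))   peaks$name   <- if (n) paste0(factor, "_peak_", seq_len(n)) else character(0)
  if (is.null(peaks$score))  peaks$score  <- rep(0L, n)
  if (is.null(peaks$strand)) peaks$strand <- rep(".", n)
  if (is.null(peaks$signal)) peaks$signal <- rep(1, n)
  if (is.null(peaks$pvalue)) peaks$pvalue <- rep(-1, n)
  if (is.null(peaks$qvalue)) peaks$qvalue <- rep(-1, n)
  if (is.null(peaks$summit)) peaks$summit <- len %/% 2L
  if (n) {
    if (anyNA(peaks$signal) || any(is.nan(peaks$signal)) || any(peaks$signal < 0)) {
      stop("peak signals must be non-negative and non-missing", call. = FALSE)
    }
    if (any(peaks$summit < 0 | peaks$summit >= len)) {
      stop("summit offsets must lie inside their peak interval", call. = FALSE)
    }
  }
  core <- c("chrom", "start", "end", "name", "score", "strand",
            "signal", "pvalue", "qvalue", "summit")
  peaks <- peaks[, c(core, setdiff(names(peaks), core)), drop = FALSE]
  structure(peaks,
            factor = factor, cell_type = cell_type,
            dataset = if (is.null(dataset)) paste(factor, cell_type, sep = ".") else dataset,
            class = c("peak_set", "data.frame"))
}

#' Peak-set metadata accessors
#' @param x a [peak_set()].
#' @return The factor name, cell-type label or dataset identifier.
#' @export
ps_factor <- function(x) attr(x, "factor")

#' @rdname ps_factor
#' @export
ps_cell_type <- function(x) attr(x, "cell_type")

#' @rdname ps_factor
#' @export
ps_dataset <- function(x) attr(x, "dataset")

#' Re-center peaks on their summit at a fixed width
#'
#' Implements the stringent-overlap convention of resizing every peak to a
#' fixed width around its summit (e.g. 200 bp by extending 100 bp in each
#' direction, or 500 bp for ChIA-PET peaks). Intervals are clipped at
#' chromosome boundaries rather than discarded, so peaks near telomeres are
#' kept at reduced width; odd widths put the extra base on the right.
#'
#' @param peaks a [peak_set()] or data.frame with `chrom`, `start`, `end`,
#'   `summit` columns.
#' @param width target width in bp (positive integer).
#' @param sizes optional named vector of chromosome lengths used for
#'   right-boundary clipping; every peak chromosome must be present. With
#'   `NULL`, only the left boundary (0) is enforced.
#' @return The input with intervals replaced by summit-centered windows and
#'   `summit` offsets updated; all other columns (signal, name, ...) kept.
#' @examples
#' ps <- peak_set(data.frame(chrom = "chr1", start = 1000, end = 2000,
#'                           summit = 500))
#' resize_to_summit(ps, 200, c(chr1 = 1e6))  # chr1:1400-1600
#' @export
resize_to_summit <- function(peaks, width, sizes = NULL) {
  .check_intervals(peaks, "peaks")
  if (length(width) != 1L || is.na(width) || width < 1) {
    stop("width must be a single positive integer", call. = FALSE)
  }
  width <- as.integer(width)
  if (!is.null(sizes)) {
    unknown <- setdiff(unique(as.character(peaks$chrom)), names(sizes))
    if (length(unknown)) {
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!nrow(peaks)) return(peaks)
  if (is.null(peaks$summit)) peaks$summit <- (peaks$end - peaks$start) %/% 2L
  summit_abs <- peaks$start + peaks$summit
  new_start <- summit_abs - width %/% 2L
  new_end <- new_start + width
  new_start <- pmax(new_start, 0L)
  if (!is.null(sizes)) {
    new_end <- pmin(new_end, unname(sizes[as.character(peaks$chrom)]))
  }
  peaks$start <- as.integer(new_start)
  peaks$end <- as.integer(new_end)
  peaks$summit <- as.integer(summit_abs - new_start)
  peaks
}

#' Do two genomic intervals overlap?
#'
#' Half-open (bedtools-intersect) semantics: intervals on the same
#' chromosome sharing at least one base. Bookended intervals do not overlap.
#'
#' @param a,b single intervals: lists or one-row data.frames with `chrom`,
#'   `start`, `end`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' overlaps(list(chrom = "chr1", start = 0, end = 10),
#'          list(chrom = "chr1", start = 9, end = 20))   # TRUE
#' overlaps(list(chrom = "chr1", start = 0, end = 10),
#'          list(chrom = "chr1", start = 10, end = 20))  # FALSE
#' @export
overlaps <- function(a, b) {
  isTRUE(as.character(a$chrom[1]) == as.character(b$chrom[1]) &&
           a$start[1] < b$end[1] && b$start[1] < a$end[1])
}

#' Count query peaks overlapping a subject set
#'
#' Number of query intervals that overlap at least one subject interval;
#' each query interval is counted at most once (bedtools-intersect `-u`
#' semantics).
#'
#' @param query,subject interval data.frames (e.g. [peak_set()]s).
#' @return Integer count in `[0, nrow(query)]`.
#' @export
count_overlapping <- function(query, subject) {
  .check_intervals(query, "query")
  .check_intervals(subject, "subject")
  if (!nrow(query) || !nrow(subject)) return(0L)
  sum(.count_ov(query, subject) > 0L)
}

#' Merge overlapping or bookended intervals
#'
#' bedtools-merge default semantics: intervals chained by overlap or
#' bookending (distance 0) collapse into one region; the union of covered
#' bases is preserved exactly.
#'
#' @param x interval data.frame.
#' @return data.frame `chrom`, `start`, `end`, sorted and non-overlapping.
#' @examples
#' merge_intervals(data.frame(chrom = "chr1", start = c(0, 100),
#'                            end = c(100, 200)))  # one region chr1:0-200
#' @export
merge_intervals <- function(x) {
  .check_intervals(x, "intervals")
  if (!nrow(x)) return(.empty_intervals())
  chrom <- as.character(x$chrom)
  out <- lapply(sort(unique(chrom)), function(ch) {
    i <- which(chrom == ch)
    # min.gapwidth = 1 (the default): bookended intervals merge
    r <- IRanges::reduce(IRanges::IRanges(x$start[i] + 1L, x$end[i]))
    data.frame(chrom = ch, start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Drop peaks overlapping excluded regions
#'
#' Generic exclude filter (e.g. for blacklist BED files or unwanted
#' chromosomes): removes every row of `x` overlapping at least one region.
#'
#' @param x interval data.frame (a [peak_set()] keeps its class).
#' @param regions interval data.frame of regions to exclude.
#' @return `x` without the overlapping rows.
#' @export
exclude_regions <- function(x, regions) {
  .check_intervals(x, "x")
  .check_intervals(regions, "regions")
  if (!nrow(x) || !nrow(regions)) return(x)
  hit <- .count_ov(x, regions) > 0L
  x[!hit, , drop = FALSE]
}
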