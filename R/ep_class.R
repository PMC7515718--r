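## Enhancer-promoter loop extraction and the five-way positional
## classification of CTCF loops against EP loops.

#' Candidate promoter regions around TSS
#'
#' Extracts the +/- `flank` bp window around every TSS (one region per
#' transcript, not merged), clipped at chromosome boundaries.
#'
#' @param tss data.frame of TSS positions: `chrom`, `start` (`end`
#'   optional; the TSS is taken at `start`), optional `name`.
#' @param flank half-width in bp (default 500).
#' @param sizes optional chromosome lengths.
#' @return data.frame of promoter intervals, one per input row.
#' @export
candidate_promoters <- function(tss, flank = 500L, sizes = NULL) {
  stopifnot(all(c("chrom", "start") %in% names(tss)), flank > 0)
  pos <- tss$start
  if (!is.null(sizes)) {
    unknown <- setdiff(unique(as.character(tss$chrom)), names(sizes))
    if (length(unknown)) {
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- data.frame(chrom = tss$chrom,
                    start = pmax(pos - flank, 0L),
                    end = pos + flank,
                    stringsAsFactors = FALSE)
  if (!is.null(sizes)) {
    out$end <- pmin(out$end, unname(sizes[as.character(tss$chrom)]))
  }
  out$name <- if (!is.null(tss$name)) tss$name else
    paste0("promoter_", seq_len(nrow(out)))
  out
}

#' Select active elements by transcription evidence
#'
#' Keeps candidate promoter/enhancer regions that intersect at least one
#' actively transcribed interval (e.g. GRO-seq-derived transcripts).
#'
#' @param candidates interval data.frame.
#' @param transcribed interval data.frame of transcribed regions.
#' @return The retained candidates.
#' @export
active_elements <- function(candidates, transcribed) {
  .check_intervals(candidates, "candidates")
  .check_intervals(transcribed, "transcribed")
  if (!nrow(candidates) || !nrow(transcribed)) {
    return(candidates[integer(0), , drop = FALSE])
  }
  hit <- .count_ov(candidates, transcribed) > 0L
  out <- candidates[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract and expand enhancer-promoter loops
#'
#' A loop qualifies when one anchor hits at least one active enhancer and
#' the other anchor hits at least one active promoter (a single anchor
#' hitting both element types does not qualify by itself). Because loop
#' anchors at 10 kb resolution may contain multiple elements, each
#' qualifying loop is expanded into one EP loop per (enhancer, promoter)
#' combination, over both orientations.
#'
#' @param loops a [loop_set()].
#' @param promoters,enhancers active element data.frames (with `name`).
#' @return data.frame of EP loops: `source_loop_id`, `enhancer_id`,
#'   `promoter_id` and both anchor intervals
#'   (`enh_chrom`/`enh_start`/`enh_end` = the anchor containing the
#'   enhancer, `prom_*` likewise).
#' @export
extract_ep_loops <- function(loops, promoters, enhancers) {
  .check_intervals(promoters, "promoters")
  .check_intervals(enhancers, "enhancers")
  n <- nrow(loops)
  empty <- data.frame(source_loop_id = character(0),
                      enhancer_id = character(0), promoter_id = character(0),
                      enh_chrom = character(0), enh_start = integer(0),
                      enh_end = integer(0), prom_chrom = character(0),
                      prom_start = integer(0), prom_end = integer(0),
                      stringsAsFactors = FALSE)
  if (!n) return(empty)
  if (is.null(promoters$name)) promoters$name <- paste0("promoter_", seq_len(nrow(promoters)))
  if (is.null(enhancers$name)) enhancers$name <- paste0("enhancer_", seq_len(nrow(enhancers)))
  anchor <- function(side) {
    data.frame(chrom = loops[[paste0("chrom", side)]],
               start = loops[[paste0("start", side)]],
               end = loops[[paste0("end", side)]])
  }
  hits_of <- function(side, elements) {
    if (!nrow(elements)) return(split(integer(0), factor(integer(0), levels = seq_len(n))))
    h <- .find_ov(anchor(side), elements)
    split(h$subject, factor(h$query, levels = seq_len(n)))
  }
  enh_a <- hits_of(1, enhancers); enh_b <- hits_of(2, enhancers)
  prom_a <- hits_of(1, promoters); prom_b <- hits_of(2, promoters)
  ids <- if (!is.null(loops$name)) loops$name else paste0("loop_", seq_len(n))
  out <- list()
  emit <- function(l, enh_idx, prom_idx, enh_side, prom_side) {
    if (!length(enh_idx) || !length(prom_idx)) return()
    grid <- expand.grid(e = enh_idx, p = prom_idx)
    ea <- anchor(enh_side)[l, ]; pa <- anchor(prom_side)[l, ]
    out[[length(out) + 1L]] <<- data.frame(
      source_loop_id = ids[l],
      enhancer_id = enhancers$name[grid$e],
      promoter_id = promoters$name[grid$p],
      enh_chrom = ea$chrom, enh_start = ea$start, enh_end = ea$end,
      prom_chrom = pa$chrom, prom_start = pa$start, prom_end = pa$end,
      stringsAsFactors = FALSE)
  }
  for (l in seq_len(n)) {
    emit(l, enh_a[[l]], prom_b[[l]], 1, 2)   # enhancer on A, promoter on B
    emit(l, enh_b[[l]], prom_a[[l]], 2, 1)   # enhancer on B, promoter on A
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## orient a loop's anchors by genomic order and compute its span
.loop_spans <- function(chrom1, start1, end1, chrom2, start2, end2) {
  swap <- chrom2 < chrom1 | (chrom2 == chrom1 & start2 < start1)
  a_chrom <- ifelse(swap, chrom2, chrom1)
  a_start <- ifelse(swap, start2, start1)
  a_end <- ifelse(swap, end2, end1)
  b_chrom <- ifelse(swap, chrom1, chrom2)
  b_start <- ifelse(swap, start1, start2)
  b_end <- ifelse(swap, end1, end2)
  list(a_chrom = a_chrom, a_start = a_start, a_end = a_end,
       b_chrom = b_chrom, b_start = b_start, b_end = b_end,
       span_start = pmin(a_start, b_start),
       span_end = pmax(a_end, b_end),
       intra = a_chrom == b_chrom)
}

#' Classify the positional relation of CTCF loops to EP loops
#'
#' Five categories, evaluated in the fixed precedence order 4 > 1 > 2 >
#' 3 > 5 on genomically oriented loops:
#' \describe{
#'   \item{4 (same)}{both anchor pairs reciprocally overlap (first anchor
#'     with first anchor, second with second, >= 1 bp each).}
#'   \item{1 (CTCF contains EP)}{the EP loop span lies inside the CTCF
#'     loop span (and the spans differ).}
#'   \item{2 (EP contains CTCF)}{the CTCF span lies inside the EP span.}
#'   \item{3 (intersecting)}{the spans overlap without containment.}
#'   \item{5 (separate)}{the spans are disjoint, or the loops involve
#'     different chromosomes.}
#' }
#' Every pair receives exactly one category; the category is invariant
#' under swapping either loop's anchors, and exchanging the roles of the
#' two loops maps 1 <-> 2 while fixing 3, 4 and 5.
#'
#' @param ctcf_loops data.frame with `chrom1`/`start1`/`end1`/`chrom2`/
#'   `start2`/`end2` (rows recycled against `ep_loops` must match).
#' @param ep_loops data.frame with the EP anchor columns `enh_chrom`,
#'   `enh_start`, `enh_end`, `prom_chrom`, `prom_start`, `prom_end` (as
#'   from [extract_ep_loops()]) or plain `chrom1`-style columns.
#' @return Integer vector of categories in `{1, 2, 3, 4, 5}`, one per
#'   row pair.
#' @export
classify_relation <- function(ctcf_loops, ep_loops) {
  ep <- if (all(c("enh_chrom", "prom_chrom") %in% names(ep_loops))) {
    data.frame(chrom1 = ep_loops$enh_chrom, start1 = ep_loops$enh_start,
               end1 = ep_loops$enh_end, chrom2 = ep_loops$prom_chrom,
               start2 = ep_loops$prom_start, end2 = ep_loops$prom_end,
               stringsAsFactors = FALSE)
  } else ep_loops
  stopifnot(nrow(ctcf_loops) == nrow(ep))
  C <- .loop_spans(as.character(ctcf_loops$chrom1), ctcf_loops$start1,
                   ctcf_loops$end1, as.character(ctcf_loops$chrom2),
                   ctcf_loops$start2, ctcf_loops$end2)
  E <- .loop_spans(as.character(ep$chrom1), ep$start1, ep$end1,
                   as.character(ep$chrom2), ep$start2, ep$end2)
  same_chrom <- C$intra & E$intra & C$a_chrom == E$a_chrom
  ov <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  reciprocal <- same_chrom &
    ov(C$a_start, C$a_end, E$a_start, E$a_end) &
    ov(C$b_start, C$b_end, E$b_start, E$b_end)
  contains <- function(os, oe, is, ie) {       # inner inside outer, not equal
    os <= is & ie <= oe & (os < is | ie < oe)
  }
  c_contains_e <- same_chrom & contains(C$span_start, C$span_end,
                                        E$span_start, E$span_end)
  e_contains_c <- same_chrom & contains(E$span_start, E$span_end,
                                        C$span_start, C$span_end)
  spans_overlap <- same_chrom & ov(C$span_start, C$span_end,
                                   E$span_start, E$span_end)
  out <- rep(5L, nrow(ep))
  out[spans_overlap] <- 3L
  out[e_contains_c] <- 2L
  out[c_contains_e] <- 1L
  out[reciprocal] <- 4L
  out
}

#' All-pairs relation table
#'
#' Classifies every (CTCF loop, EP loop) pair.
#'
#' @param ctcf_loops a [loop_set()] (e.g. decreased differential loops).
#' @param ep_loops output of [extract_ep_loops()].
#' @return data.frame `ctcf_loop_id`, `ep_loop_id`, `category`.
#' @export
relation_table <- function(ctcf_loops, ep_loops) {
  nc <- nrow(ctcf_loops); ne <- nrow(ep_loops)
  if (!nc || !ne) {
    return(data.frame(ctcf_loop_id = character(0),
                      ep_loop_id = character(0), category = integer(0)))
  }
  ci <- rep(seq_len(nc), each = ne)
  ei <- rep(seq_len(ne), times = nc)
  cid <- if (!is.null(ctcf_loops$name)) ctcf_loops$name else
    paste0("ctcf_loop_", seq_len(nc))
  eid <- if (!is.null(ep_loops$ep_id)) ep_loops$ep_id else
    paste0(ep_loops$source_loop_id %||% "ep", "_",
           ep_loops$enhancer_id %||% seq_len(ne), "_",
           ep_loops$promoter_id %||% "")
  data.frame(ctcf_loop_id = cid[ci],
             ep_loop_id = eid[ei],
             category = classify_relation(ctcf_loops[ci, , drop = FALSE],
                                          ep_loops[ei, , drop = FALSE]),
             stringsAsFactors = FALSE)
}

#' Summarize relation categories
#'
#' Per-category pair counts plus a per-CTCF-loop rollup of the categories
#' it participates in (a loop may appear in several categories across its
#' EP-loop pairings).
#'
#' @param relations output of [relation_table()].
#' @return list with `counts` (named count per category 1-5) and
#'   `per_ctcf_loop` (data.frame `ctcf_loop_id`, `categories` list
#'   column of sorted distinct categories).
#' @export
relation_summary <- function(relations) {
  counts <- setNames(integer(5), as.character(1:5))
  tab <- table(factor(relations$category, levels = 1:5))
  counts[] <- as.integer(tab)
  ids <- unique(relations$ctcf_loop_id)
  per <- data.frame(ctcf_loop_id = ids, stringsAsFactors = FALSE)
  per$categories <- lapply(ids, function(id) {
    sort(unique(relations$category[relations$ctcf_loop_id == id]))
  })
  list(counts = counts, per_ctcf_loop = per)
}
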