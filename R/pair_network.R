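## Factor-pair analysis at paired loop anchors: every pair of factors
## bound across the two anchors of a loop is scored with that loop's
## strength; scores are summed per unordered pair into a network.

#' Factors bound at an anchor
#'
#' @param anchor single interval (list or one-row data.frame).
#' @param factor_sets named list of [peak_set()]s.
#' @return Character vector of factor names with >= 1 peak overlapping
#'   the anchor.
#' @export
factors_at_anchor <- function(anchor, factor_sets) {
  a <- data.frame(chrom = as.character(anchor$chrom[1]),
                  start = anchor$start[1], end = anchor$end[1])
  names(which(vapply(factor_sets, function(ps) {
    count_overlapping(a, as.data.frame(ps)) > 0L
  }, logical(1))))
}

#' Score factor pairs across paired loop anchors
#'
#' For each loop with factor sets A (anchor a) and B (anchor b) and
#' strength s, every ordered cross-product occurrence (x in A, y in B)
#' contributes s to the canonical unordered edge \{x, y\}; self-pairs
#' (x = x) are retained since they carry the homotypic (e.g. CTCF-CTCF)
#' signal. The total over all edges therefore equals
#' sum over loops of s * |A| * |B| exactly, and the result is invariant
#' under swapping anchor labels.
#'
#' @param loops a [loop_set()].
#' @param factor_sets named list of [peak_set()]s.
#' @param strength per-loop scores (default the PET counts).
#' @return data.frame of edges: `factor_x`, `factor_y` (with
#'   `factor_x <= factor_y`), `score`, `n_loops` (number of distinct
#'   supporting loops), ordered by score descending then names.
#' @export
pair_scores <- function(loops, factor_sets,
                        strength = loops$pet_count) {
  stopifnot(is.list(factor_sets), !is.null(names(factor_sets)))
  n <- nrow(loops)
  stopifnot(length(strength) == n, all(strength >= 0))
  empty <- data.frame(factor_x = character(0), factor_y = character(0),
                      score = numeric(0), n_loops = integer(0),
                      stringsAsFactors = FALSE)
  if (!n || !length(factor_sets)) return(empty)
  ## membership matrices (loop-end x factor) from one overlap join
  ends <- data.frame(chrom = c(loops$chrom1, loops$chrom2),
                     start = c(loops$start1, loops$start2),
                     end = c(loops$end1, loops$end2))
  nf <- length(factor_sets)
  all_peaks <- do.call(rbind, lapply(seq_len(nf), function(k) {
    ps <- factor_sets[[k]]
    if (!nrow(ps)) return(NULL)
    data.frame(chrom = as.character(ps$chrom), start = ps$start,
               end = ps$end, fi = k, stringsAsFactors = FALSE)
  }))
  mem <- matrix(FALSE, 2L * n, nf, dimnames = list(NULL, names(factor_sets)))
  if (!is.null(all_peaks) && nrow(all_peaks)) {
    hits <- .find_ov(ends, all_peaks)
    mem[cbind(hits$query, all_peaks$fi[hits$subject])] <- TRUE
  }
  mem_a <- mem[seq_len(n), , drop = FALSE]
  mem_b <- mem[n + seq_len(n), , drop = FALSE]
  score_env <- new.env(hash = TRUE, parent = emptyenv())
  loops_env <- new.env(hash = TRUE, parent = emptyenv())
  for (l in seq_len(n)) {
    A <- names(factor_sets)[mem_a[l, ]]
    B <- names(factor_sets)[mem_b[l, ]]
    if (!length(A) || !length(B)) next
    s <- strength[l]
    seen <- character(0)
    for (x in A) for (y in B) {
      k <- if (x <= y) paste(x, y, sep = "\r") else paste(y, x, sep = "\r")
      score_env[[k]] <- (score_env[[k]] %||% 0) + s
      if (!(k %in% seen)) {
        loops_env[[k]] <- (loops_env[[k]] %||% 0L) + 1L
        seen <- c(seen, k)
      }
    }
  }
  keys <- ls(score_env)
  if (!length(keys)) return(empty)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    factor_x = vapply(parts, `[[`, character(1), 1L),
    factor_y = vapply(parts, `[[`, character(1), 2L),
    score = vapply(keys, function(k) score_env[[k]], numeric(1)),
    n_loops = vapply(keys, function(k) loops_env[[k]], integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$factor_x, out$factor_y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter and export a factor-pair network
#'
#' Applies a score threshold and/or a top-edges cut and writes a
#' Cytoscape-loadable tab-separated edge list, deterministically ordered
#' by score descending then factor names.
#'
#' @param edges output of [pair_scores()].
#' @param path output file.
#' @param min_score minimal edge score kept.
#' @param top_edges maximal number of edges kept (default all).
#' @return The filtered edges, invisibly.
#' @export
export_network <- function(edges, path, min_score = 0, top_edges = Inf) {
  keep <- edges[edges$score >= min_score, , drop = FALSE]
  keep <- keep[order(-keep$score, keep$factor_x, keep$factor_y), , drop = FALSE]
  if (is.finite(top_edges)) keep <- head(keep, top_edges)
  write_edge_list(keep, path)
  invisible(keep)
}
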