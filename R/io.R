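## File I/O for the plain-text formats the pipeline touches.  All
## coordinates are 0-based half-open both on disk and in memory.

.split_lines <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

.num_or_stop <- function(x, lineno, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("malformed %s at line %d of '%s': non-numeric %s '%s'",
                 what, lineno[bad[1]], path, what, x[bad[1]]), call. = FALSE)
  }
  out
}

#' Read and write narrowPeak (BED6+4) files
#'
#' `read_narrowpeak()` parses a MACS2-style narrowPeak file into a
#' [peak_set()]. Column 7 is the signal value, column 10 the summit offset
#' from `start`; a summit of -1 falls back to the interval midpoint so that
#' plain BED-derived peak files stay usable. Malformed lines and summits
#' outside their interval raise errors naming the offending line.
#' `write_narrowpeak()` writes the ten canonical columns; the round trip
#' `read(write(x))` preserves all fields.
#'
#' @param path file path.
#' @param factor,cell_type,dataset metadata attached to the returned set.
#' @return `read_narrowpeak()`: a [peak_set()]. `write_narrowpeak()`: the
#'   path, invisibly.
#' @export
read_narrowpeak <- function(path, factor = "unknown", cell_type = "unknown",
                            dataset = NULL) {
  p <- .split_lines(path)
  if (!length(p$fields)) {
    return(peak_set(.empty_intervals(), factor, cell_type, dataset))
  }
  nf <- lengths(p$fields)
  if (any(nf != 10L)) {
    bad <- which(nf != 10L)[1]
    stop(sprintf("malformed narrowPeak at line %d of '%s': expected 10 fields, found %d",
                 p$lineno[bad], path, nf[bad]), call. = FALSE)
  }
  m <- matrix(unlist(p$fields), ncol = 10L, byrow = TRUE)
  start <- .num_or_stop(m[, 2], p$lineno, "start", path)
  end <- .num_or_stop(m[, 3], p$lineno, "end", path)
  summit <- .num_or_stop(m[, 10], p$lineno, "summit", path)
  len <- end - start
  summit[summit == -1] <- (len %/% 2)[summit == -1]
  outside <- which(summit < 0 | summit >= len)
  if (length(outside)) {
    stop(sprintf("summit outside interval at line %d of '%s'",
                 p$lineno[outside[1]], path), call. = FALSE)
  }
  peaks <- data.frame(
    chrom = m[, 1], start = as.integer(start), end = as.integer(end),
    name = m[, 4],
    score = as.integer(.num_or_stop(m[, 5], p$lineno, "score", path)),
    strand = m[, 6],
    signal = .num_or_stop(m[, 7], p$lineno, "signal", path),
    pvalue = .num_or_stop(m[, 8], p$lineno, "pvalue", path),
    qvalue = .num_or_stop(m[, 9], p$lineno, "qvalue", path),
    summit = as.integer(summit),
    stringsAsFactors = FALSE)
  peak_set(peaks, factor, cell_type, dataset)
}

#' @rdname read_narrowpeak
#' @param x a [peak_set()] (or compatible data.frame).
#' @export
write_narrowpeak <- function(x, path) {
  .check_intervals(x, "peaks")
  x <- peak_set(as.data.frame(x), attr(x, "factor") %||% "unknown",
                attr(x, "cell_type") %||% "unknown", attr(x, "dataset"))
  m <- cbind(as.character(x$chrom), x$start, x$end, x$name, x$score,
             x$strand, as.character(x$signal), as.character(x$pvalue),
             as.character(x$qvalue), x$summit)
  writeLines(apply(m, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a BED file
#'
#' Accepts BED3 and wider; a 4th column is returned as `name`, a 5th as
#' `score`, a 6th as `strand`.
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end` (+ optional columns).
#' @export
read_bed <- function(path) {
  p <- .split_lines(path)
  if (!length(p$fields)) return(.empty_intervals())
  nf <- lengths(p$fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1]
    stop(sprintf("malformed BED at line %d of '%s': fewer than 3 fields",
                 p$lineno[bad], path), call. = FALSE)
  }
  nc <- min(nf)
  m <- t(vapply(p$fields, function(f) f[seq_len(nc)], character(nc)))
  out <- data.frame(chrom = m[, 1],
                    start = as.integer(.num_or_stop(m[, 2], p$lineno, "start", path)),
                    end = as.integer(.num_or_stop(m[, 3], p$lineno, "end", path)),
                    stringsAsFactors = FALSE)
  if (nc >= 4L) out$name <- m[, 4]
  if (nc >= 5L) out$score <- .num_or_stop(m[, 5], p$lineno, "score", path)
  if (nc >= 6L) out$strand <- m[, 6]
  .check_intervals(out, "BED intervals")
  out
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus `name`/`score`/`strand` when present.
#'
#' @param x interval data.frame.
#' @param path file path.
#' @export
write_bed <- function(x, path) {
  .check_intervals(x, "intervals")
  cols <- list(as.character(x$chrom), x$start, x$end)
  if (!is.null(x$name)) {
    cols <- c(cols, list(x$name))
    if (!is.null(x$score)) {
      cols <- c(cols, list(x$score))
      if (!is.null(x$strand)) cols <- c(cols, list(x$strand))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Construct a loop set
#'
#' A loop is a pair of anchor intervals with a PET (paired-end tag) count —
#' the unit of all interaction data. Anchors are canonically ordered so that
#' `anchor_a` precedes `anchor_b` by (chromosome, start).
#'
#' @param loops data.frame with `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2` and optionally `name`, `pet_count` (default 1),
#'   `count_control`, `count_kd`, `fdr`.
#' @return data.frame of class `loop_set` with canonical anchor order.
#' @export
loop_set <- function(loops) {
  stopifnot(is.data.frame(loops))
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  missing <- setdiff(req, names(loops))
  if (length(missing)) {
    stop("loops lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(loops)
  if (is.null(loops$name)) loops$name <- if (n) paste0("loop_", seq_len(n)) else character(0)
  if (is.null(loops$pet_count)) loops$pet_count <- rep(1L, n)
  if (n) {
    .check_intervals(data.frame(chrom = loops$chrom1, start = loops$start1,
                                end = loops$end1), "anchor A")
    .check_intervals(data.frame(chrom = loops$chrom2, start = loops$start2,
                                end = loops$end2), "anchor B")
    if (any(loops$pet_count < 1)) {
      stop("pet_count must be >= 1", call. = FALSE)
    }
    swap <- loops$chrom2 < loops$chrom1 |
      (loops$chrom2 == loops$chrom1 & loops$start2 < loops$start1)
    if (any(swap)) {
      a <- loops[swap, c("chrom1", "start1", "end1")]
      loops[swap, c("chrom1", "start1", "end1")] <-
        loops[swap, c("chrom2", "start2", "end2")]
      loops[swap, c("chrom2", "start2", "end2")] <- a
    }
  }
  class(loops) <- c("loop_set", "data.frame")
  loops
}

#' Read and write BEDPE loop files
#'
#' The BEDPE dialect used throughout: six anchor coordinates, then `name`
#' and a score column carrying the PET count, with optional per-condition
#' counts (columns 9-10) and an FDR (column 11). Seven-column files whose
#' 7th column is numeric are accepted with the PET count in column 7.
#' Files are written with a single `#`-prefixed header line (skipped on
#' read), so an empty loop set still round-trips.
#'
#' @param path file path.
#' @return `read_bedpe_loops()`: a [loop_set()].
#' @export
read_bedpe_loops <- function(path) {
  p <- .split_lines(path)
  if (!length(p$fields)) {
    return(loop_set(data.frame(chrom1 = character(0), start1 = integer(0),
                               end1 = integer(0), chrom2 = character(0),
                               start2 = integer(0), end2 = integer(0))))
  }
  nf <- lengths(p$fields)
  if (any(nf < 6L)) {
    bad <- which(nf < 6L)[1]
    stop(sprintf("malformed BEDPE at line %d of '%s': fewer than 6 fields",
                 p$lineno[bad], path), call. = FALSE)
  }
  nc <- min(nf)
  m <- t(vapply(p$fields, function(f) f[seq_len(nc)], character(nc)))
  out <- data.frame(
    chrom1 = m[, 1],
    start1 = as.integer(.num_or_stop(m[, 2], p$lineno, "start1", path)),
    end1 = as.integer(.num_or_stop(m[, 3], p$lineno, "end1", path)),
    chrom2 = m[, 4],
    start2 = as.integer(.num_or_stop(m[, 5], p$lineno, "start2", path)),
    end2 = as.integer(.num_or_stop(m[, 6], p$lineno, "end2", path)),
    stringsAsFactors = FALSE)
  if (nc == 7L) {
    out$pet_count <- as.integer(.num_or_stop(m[, 7], p$lineno, "pet_count", path))
  } else if (nc >= 8L) {
    out$name <- m[, 7]
    out$pet_count <- as.integer(.num_or_stop(m[, 8], p$lineno, "pet_count", path))
    if (nc >= 10L) {
      out$count_control <- as.integer(.num_or_stop(m[, 9], p$lineno, "count_control", path))
      out$count_kd <- as.integer(.num_or_stop(m[, 10], p$lineno, "count_kd", path))
    }
    if (nc >= 11L) out$fdr <- .num_or_stop(m[, 11], p$lineno, "fdr", path)
  }
  loop_set(out)
}

#' @rdname read_bedpe_loops
#' @param loops a [loop_set()].
#' @export
write_bedpe_loops <- function(loops, path) {
  loops <- loop_set(as.data.frame(loops))
  header <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
              "name", "pet_count")
  cols <- list(as.character(loops$chrom1), loops$start1, loops$end1,
               as.character(loops$chrom2), loops$start2, loops$end2,
               loops$name, loops$pet_count)
  if (!is.null(loops$count_control) && !is.null(loops$count_kd)) {
    header <- c(header, "count_control", "count_kd")
    cols <- c(cols, list(loops$count_control, loops$count_kd))
    if (!is.null(loops$fdr)) {
      header <- c(header, "fdr")
      cols <- c(cols, list(as.character(loops$fdr)))
    }
  }
  body <- if (nrow(loops)) do.call(paste, c(cols, sep = "\t")) else character(0)
  writeLines(c(paste0("#", paste(header, collapse = "\t")), body), path)
  invisible(path)
}

#' Read and write factor-pair edge lists
#'
#' Tab-separated `factor_x  factor_y  score  n_loops` with a header row;
#' directly loadable by Cytoscape as a network table.
#'
#' @param path file path.
#' @return `read_edge_list()`: data.frame of edges.
#' @export
read_edge_list <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(out) <- c("factor_x", "factor_y", "score", "n_loops")
  out
}

#' @rdname read_edge_list
#' @param edges data.frame with `factor_x`, `factor_y`, `score`, `n_loops`.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges[, c("factor_x", "factor_y", "score", "n_loops")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
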