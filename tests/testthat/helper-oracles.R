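# Brute-force oracles and small random-instance generators shared by the
# unit and property tests.  Oracles are deliberately naive (per-pair double
# loops, per-base painting) and independent of the package's interval
# machinery.

rand_intervals <- function(n, chroms = c("chrA", "chrB"), chrom_len = 1e5,
                           max_width = 400L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width,
             stringsAsFactors = FALSE)
}

rand_peaks <- function(n, ...) {
  x <- rand_intervals(n, ...)
  x$signal <- round(rlnorm(n, 2, 1), 4)
  x$summit <- as.integer(floor((x$end - x$start) / 2))
  x
}

# O(n^2) all-pairs overlap: number of query rows overlapping >= 1 subject row
oracle_count_overlapping <- function(query, subject) {
  if (!nrow(query) || !nrow(subject)) return(0L)
  hit <- vapply(seq_len(nrow(query)), function(i) {
    any(query$chrom[i] == subject$chrom &
          query$start[i] < subject$end & subject$start < query$end[i])
  }, logical(1))
  sum(hit)
}

# paint bases on a boolean mask, then extract runs
oracle_merge <- function(x, chrom_len = 1e5) {
  out <- lapply(sort(unique(x$chrom)), function(ch) {
    mask <- logical(chrom_len)
    for (i in which(x$chrom == ch)) {
      mask[(x$start[i] + 1):x$end[i]] <- TRUE
    }
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep] - 1L, end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# per-site per-segment base-overlap tally, collapsed to the five categories
oracle_state_category <- function(sites, segments) {
  map <- c(TssA = "promoter", TssFlnk = "promoter", TssFlnkU = "promoter",
           TssFlnkD = "promoter", TssBiv = "promoter",
           EnhG1 = "enhancer", EnhG2 = "enhancer", EnhA1 = "enhancer",
           EnhA2 = "enhancer", EnhWk = "enhancer", EnhBiv = "enhancer",
           Tx = "transcription", TxWk = "transcription",
           ReprPCWk = "reprPCWk")
  levels <- c("promoter", "enhancer", "transcription", "reprPCWk", "quies")
  vapply(seq_len(nrow(sites)), function(i) {
    bases <- setNames(numeric(5), levels)
    for (j in seq_len(nrow(segments))) {
      if (sites$chrom[i] != segments$chrom[j]) next
      ov <- min(sites$end[i], segments$end[j]) -
        max(sites$start[i], segments$start[j])
      if (ov > 0) {
        cat_j <- map[segments$name[j]]
        if (is.na(cat_j)) cat_j <- "quies"
        bases[cat_j] <- bases[cat_j] + ov
      }
    }
    if (all(bases == 0)) "quies" else levels[which.max(bases)]
  }, character(1))
}

# triple-loop factor-pair accumulation
oracle_pair_scores <- function(loop_factors_a, loop_factors_b, strengths) {
  acc <- list()
  for (l in seq_along(strengths)) {
    for (x in loop_factors_a[[l]]) for (y in loop_factors_b[[l]]) {
      k <- paste(sort(c(x, y)), collapse = "|")
      acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + strengths[l]
    }
  }
  acc
}

# a tiny deterministic peak-set builder
mk_peaks <- function(chrom, start, end, signal = 1, summit = NULL,
                     factor = "X", cell_type = "ct", ...) {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   signal = signal, stringsAsFactors = FALSE)
  if (!is.null(summit)) df$summit <- summit
  peak_set(df, factor = factor, cell_type = cell_type, ...)
}
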