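## Candidate regulatory modules: summit-resized peaks from all factors are
## merged into regulatory regions; CTCF CRMs are clustered by co-binding
## density into dense / medium / light / CTCF-solo groups.

#' Build candidate regulatory modules
#'
#' Resizes every peak of every factor to `peak_width` around its summit
#' (100 bp by default, which keeps nearby modules from merging into
#' overly long regions) and merges the resized peaks into CRMs. Every
#' input peak falls into exactly one CRM.
#'
#' @param factor_sets named list of [peak_set()]s (all factors, including
#'   CTCF and cohesin if available).
#' @param peak_width resize width in bp (100, 150 or 200 are the standard
#'   choices; any positive value is accepted).
#' @param sizes optional chromosome lengths for clipping.
#' @return data.frame of CRMs: `chrom`, `start`, `end`, `width`,
#'   `n_factors` and a list column `member_factors`.
#' @export
build_crms <- function(factor_sets, peak_width = 100L, sizes = NULL) {
  stopifnot(is.list(factor_sets))
  if (is.null(names(factor_sets)) || any(!nzchar(names(factor_sets)))) {
    names(factor_sets) <- vapply(factor_sets, function(ps) {
      attr(ps, "factor") %||% "unknown"
    }, character(1))
  }
  resized <- lapply(factor_sets, function(ps) {
    if (!nrow(ps)) return(NULL)
    r <- resize_to_summit(as.data.frame(ps), peak_width, sizes)
    r[, c("chrom", "start", "end")]
  })
  resized <- resized[!vapply(resized, is.null, logical(1))]
  all_peaks <- if (length(resized)) {
    do.call(rbind, c(resized, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(all_peaks) || !nrow(all_peaks)) {
    out <- .empty_intervals()
    out$width <- integer(0); out$n_factors <- integer(0)
    out$member_factors <- list()
    return(out)
  }
  crms <- merge_intervals(all_peaks)
  members <- vector("list", nrow(crms))
  for (fn in names(resized)) {
    r <- resized[[fn]]
    if (is.null(r)) next
    idx <- unique(.find_ov(crms, r)$query)
    for (i in idx) members[[i]] <- c(members[[i]], fn)
  }
  crms$width <- crms$end - crms$start
  crms$n_factors <- lengths(members)
  crms$member_factors <- members
  crms
}

#' Select CTCF CRMs
#'
#' Keeps CRMs containing exactly one CTCF peak (regions with two or more
#' CTCF sites are ambiguous and dropped), optionally additionally
#' requiring a cohesin peak and/or overlap with CTCF ChIA-PET peaks.
#'
#' @param crms output of [build_crms()].
#' @param ctcf CTCF [peak_set()] used to count CTCF peaks per CRM.
#' @param cohesin optional cohesin (e.g. RAD21) peak set.
#' @param chiapet_peaks optional ChIA-PET peak intervals.
#' @param require_cohesin,require_chiapet apply the optional filters.
#' @return The retained CRMs with columns `ctcf_index` (row of `ctcf`),
#'   `ctcf_signal`, `has_cohesin`, `overlaps_chiapet`.
#' @export
select_ctcf_crms <- function(crms, ctcf, cohesin = NULL,
                             chiapet_peaks = NULL,
                             require_cohesin = FALSE,
                             require_chiapet = FALSE) {
  .check_intervals(crms, "crms")
  if (require_cohesin && is.null(cohesin)) {
    stop("require_cohesin = TRUE but no cohesin peaks given", call. = FALSE)
  }
  if (require_chiapet && is.null(chiapet_peaks)) {
    stop("require_chiapet = TRUE but no ChIA-PET peaks given", call. = FALSE)
  }
  if (!nrow(crms)) return(crms)
  hits <- .find_ov(crms, ctcf)
  n_ctcf <- tabulate(hits$query, nbins = nrow(crms))
  keep <- n_ctcf == 1L
  ctcf_index <- rep(NA_integer_, nrow(crms))
  single <- hits$query %in% which(keep)
  ctcf_index[hits$query[single]] <- hits$subject[single]
  crms$ctcf_index <- ctcf_index
  crms$ctcf_signal <- ifelse(is.na(ctcf_index), NA_real_, ctcf$signal[ctcf_index])
  crms$has_cohesin <- if (is.null(cohesin)) NA else
    .count_ov(crms, cohesin) > 0L
  crms$overlaps_chiapet <- if (is.null(chiapet_peaks)) NA else
    .count_ov(crms, chiapet_peaks) > 0L
  if (require_cohesin) keep <- keep & crms$has_cohesin
  if (require_chiapet) keep <- keep & crms$overlaps_chiapet
  out <- crms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Central width interval of CRMs
#'
#' The symmetric percentile pair containing `central_mass` of CRM widths
#' (e.g. 0.90 gives the 5th and 95th percentiles), computed with the
#' standard linear-interpolation percentile.
#'
#' @param crms data.frame with a `width` column (or `end - start`).
#' @param central_mass central probability mass, in `(0, 1]`.
#' @return Numeric `c(low, high)`.
#' @export
width_percentile_interval <- function(crms, central_mass = 0.90) {
  stopifnot(central_mass > 0, central_mass <= 1)
  w <- if (!is.null(crms$width)) crms$width else crms$end - crms$start
  lo <- (1 - central_mass) / 2
  unname(quantile(w, c(lo, 1 - lo), type = 7))
}

#' Binary CRM x factor co-binding matrix
#'
#' @param crms output of [build_crms()] (needs `member_factors`).
#' @param factor_panel character vector of factor names (columns).
#' @return 0/1 integer matrix, one row per CRM.
#' @export
crm_matrix <- function(crms, factor_panel) {
  stopifnot(length(factor_panel) >= 1L)
  m <- vapply(factor_panel, function(fn) {
    as.integer(vapply(crms$member_factors, function(mm) fn %in% mm, logical(1)))
  }, integer(nrow(crms)))
  m <- matrix(m, nrow = nrow(crms),
              dimnames = list(NULL, factor_panel))
  m
}

#' Cluster CRMs into co-binding density groups
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances between binary co-binding rows), cut at `k` groups; clusters
#' are relabeled dense > medium > light > ctcf_solo by descending mean
#' co-binding count, so the labels are comparable across runs.
#'
#' @param crms output of [build_crms()] / [select_ctcf_crms()].
#' @param factor_panel factor names used as clustering features.
#' @param k number of groups (default 4).
#' @return Character vector of group labels, one per CRM (levels `dense`,
#'   `medium`, `light`, `ctcf_solo` for k = 4; `group1` > `group2` > ...
#'   otherwise).
#' @export
cluster_crms <- function(crms, factor_panel, k = 4L) {
  if (!length(factor_panel)) stop("factor panel is empty", call. = FALSE)
  if (nrow(crms) < k) {
    stop("fewer CRMs than clusters requested", call. = FALSE)
  }
  m <- crm_matrix(crms, factor_panel)
  if (nrow(unique(m)) < k) {
    stop("fewer than k distinct co-binding profiles; k unreachable",
         call. = FALSE)
  }
  hc <- hclust(dist(m), method = "ward.D2")
  cl <- cutree(hc, k = k)
  mean_count <- tapply(rowSums(m), cl, mean)
  ord <- order(-mean_count)            # densest cluster first
  labels <- if (k == 4L) c("dense", "medium", "light", "ctcf_solo") else
    paste0("group", seq_len(k))
  map <- setNames(labels, names(mean_count)[ord])
  unname(map[as.character(cl)])
}

#' Pairwise group comparisons by Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test for every pair of groups on a per-CRM
#' value (CTCF peak signal, anchor loop strength, ...). Pairs involving an
#' empty group are skipped with a warning.
#'
#' @param values numeric vector, one value per CRM.
#' @param labels group label per CRM.
#' @return data.frame `group1`, `group2`, `n1`, `n2`, `statistic`, `p`.
#' @export
compare_groups <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  groups <- unique(labels[!is.na(labels)])
  out <- list()
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    x <- values[labels == groups[i] & !is.na(values)]
    y <- values[labels == groups[j] & !is.na(values)]
    if (!length(x) || !length(y)) {
      warning("skipping pair with empty group: ", groups[i], " vs ",
              groups[j], call. = FALSE)
      next
    }
    wt <- wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      group1 = groups[i], group2 = groups[j],
      n1 = length(x), n2 = length(y),
      statistic = unname(wt$statistic), p = wt$p.value,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(group1 = character(0), group2 = character(0),
                      n1 = integer(0), n2 = integer(0),
                      statistic = numeric(0), p = numeric(0)))
  }
  do.call(rbind, out)
}
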