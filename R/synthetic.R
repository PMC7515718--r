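## Synthetic-data generator.  Every downstream statistic in the package is
## exercised on data produced here, with the planted structure returned as
## ground truth.  One root seed drives the whole simulation; each output
## draws from its own sub-stream (a fixed hash of the root seed and a
## stream label), so adding a new output never perturbs existing ones.

#' Derive a deterministic sub-stream seed
#' @noRd
.stream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2011 + h) %% 2147483647L
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults are
#' the study conditions used throughout the package's validation: a 2 x
#' 10 Mb genome, 2000 CTCF sites conserved across 4 cell types at
#' probability 0.9 with lognormal binding signal, a six-factor panel with
#' planted co-binding fractions spanning 0.05-0.95 plus 500 background
#' peaks each, 2000 loops anchored on CTCF sites with PET counts
#' 1 + Poisson(4) doubled at anchors bound by the planted loop-promoting
#' factor, a 10% planted differential-loop fraction at fold 8, and 400
#' TSS / 400 enhancers of which half are actively transcribed.
#'
#' @param seed integer root seed; identical configurations produce
#'   byte-identical outputs.
#' @param genome named vector of chromosome lengths (bp).
#' @param n_ctcf number of master CTCF sites.
#' @param n_cell_types number of cell types in the compendium.
#' @param conservation_prob probability a site is present in a cell type.
#' @param signal_meanlog,signal_sdlog lognormal signal parameters.
#' @param conservation_signal_coupling logit-scale coupling between a
#'   site's signal z-score and its presence probability; 0 decouples them
#'   (presence exactly Binomial), positive values make strong sites more
#'   conserved.
#' @param factor_specs list of `list(name=, f=, n_extra=)`: each simulated
#'   factor plants `round(f * n_ctcf)` peaks on CTCF summits and adds
#'   `n_extra` background peaks away from CTCF.
#' @param loop_spec list with `n_loops`, `anchor_width`, `pet_lambda`
#'   (PET count is 1 + Poisson(lambda)), `loop_boost` (multiplier applied
#'   once per promoting factor bound at either anchor), `promoting_factors`
#'   (character), `max_span` (maximal anchor separation, bp).
#' @param diff_spec list with `diff_fraction` (fraction of loops given a
#'   planted condition effect) and `fold` (mean fold change).
#' @param ep_spec list with `n_tss`, `n_enhancers`, `active_fraction`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(chr1 = 10e6, chr2 = 10e6),
                       n_ctcf = 2000L,
                       n_cell_types = 4L,
                       conservation_prob = 0.9,
                       signal_meanlog = 3,
                       signal_sdlog = 0.5,
                       conservation_signal_coupling = 1,
                       factor_specs = list(
                         list(name = "F05", f = 0.05, n_extra = 500L),
                         list(name = "F20", f = 0.20, n_extra = 500L),
                         list(name = "F40", f = 0.40, n_extra = 500L),
                         list(name = "F60", f = 0.60, n_extra = 500L),
                         list(name = "F80", f = 0.80, n_extra = 500L),
                         list(name = "F95", f = 0.95, n_extra = 500L)),
                       loop_spec = list(n_loops = 2000L, anchor_width = 500L,
                                        pet_lambda = 4, loop_boost = 2,
                                        promoting_factors = "F20",
                                        max_span = 2e6),
                       diff_spec = list(diff_fraction = 0.1, fold = 8),
                       ep_spec = list(n_tss = 400L, n_enhancers = 400L,
                                      active_fraction = 0.5)) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            length(genome) >= 1L, all(genome > 0), !is.null(names(genome)),
            n_ctcf >= 1L, n_cell_types >= 1L,
            conservation_prob >= 0, conservation_prob <= 1,
            signal_sdlog >= 0,
            loop_spec$n_loops >= 0, loop_spec$anchor_width >= 2,
            loop_spec$pet_lambda >= 0, loop_spec$loop_boost > 0,
            diff_spec$diff_fraction >= 0, diff_spec$diff_fraction <= 1,
            diff_spec$fold >= 1,
            ep_spec$n_tss >= 1, ep_spec$n_enhancers >= 1,
            ep_spec$active_fraction >= 0, ep_spec$active_fraction <= 1)
  for (fs in factor_specs) {
    stopifnot(!is.null(fs$name), fs$f >= 0, fs$f <= 1, fs$n_extra >= 0)
  }
  if (is.null(loop_spec$max_span)) loop_spec$max_span <- 2e6
  structure(list(seed = as.integer(seed), genome = genome,
                 n_ctcf = as.integer(n_ctcf),
                 n_cell_types = as.integer(n_cell_types),
                 conservation_prob = conservation_prob,
                 signal_meanlog = signal_meanlog,
                 signal_sdlog = signal_sdlog,
                 conservation_signal_coupling = conservation_signal_coupling,
                 factor_specs = factor_specs, loop_spec = loop_spec,
                 diff_spec = diff_spec, ep_spec = ep_spec),
            class = "sim_config")
}

## Master sites sit one per slot on a per-chromosome grid with a 600 bp
## margin, guaranteeing >= 1.2 kb summit separation: anchors stay
## unambiguous and planted overlap fractions are uncontaminated.
.place_master_sites <- function(config) {
  genome <- config$genome
  n_per <- round(config$n_ctcf * genome / sum(genome))
  n_per[length(n_per)] <- config$n_ctcf - sum(n_per[-length(n_per)])
  out <- lapply(seq_along(genome), function(i) {
    n <- n_per[i]
    if (n < 1) return(NULL)
    slot <- floor(genome[i] / n)
    if (slot < 1300) stop("genome too small for n_ctcf sites", call. = FALSE)
    lo <- (seq_len(n) - 1) * slot + 600
    summit <- as.integer(lo + floor(runif(n) * (slot - 1200)))
    data.frame(chrom = names(genome)[i], summit = summit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a multi-cell-type CTCF peak compendium
#'
#' Places `n_ctcf` master CTCF sites, then realizes each site in each cell
#' type with probability `conservation_prob` (optionally coupled to the
#' site's signal on the logit scale), jittering realized summits by at most
#' 50 bp. The per-site presence truth table is returned for validation.
#'
#' @param config a [sim_config()].
#' @return list with `master` (data.frame of 500 bp summit-centered sites
#'   with `signal`), `cell_types` (named list of [peak_set()], one per cell
#'   type), `truth` (logical site x cell-type presence matrix) and `sizes`
#'   (the chromosome lengths).
#' @export
simulate_compendium <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config$seed, "compendium"))
  master <- .place_master_sites(config)
  n <- nrow(master)
  z <- rnorm(n)
  summit_abs <- master$summit
  master$signal <- exp(config$signal_meanlog + config$signal_sdlog * z)
  master$start <- summit_abs - 250L
  master$end <- summit_abs + 250L
  master$summit <- 250L                   # offset from start, peak convention
  master$name <- sprintf("ctcf_site_%04d", seq_len(n))
  master <- master[, c("chrom", "start", "end", "name", "signal", "summit")]
  p <- config$conservation_prob
  prob <- if (p <= 0 || p >= 1 || config$conservation_signal_coupling == 0) {
    rep(p, n)
  } else {
    plogis(qlogis(p) + config$conservation_signal_coupling * z)
  }
  cts <- paste0("cell", seq_len(config$n_cell_types))
  truth <- matrix(FALSE, n, config$n_cell_types, dimnames = list(master$name, cts))
  cell_types <- setNames(vector("list", length(cts)), cts)
  for (j in seq_along(cts)) {
    present <- runif(n) < prob
    truth[, j] <- present
    idx <- which(present)
    jit <- sample(-50:50, length(idx), replace = TRUE)
    s <- summit_abs[idx] + jit
    peaks <- data.frame(
      chrom = master$chrom[idx],
      start = as.integer(s - 200L), end = as.integer(s + 200L),
      name = paste0(cts[j], "_", master$name[idx]),
      signal = master$signal[idx] * exp(rnorm(length(idx), 0, 0.2)),
      summit = 200L,
      site_index = idx,
      stringsAsFactors = FALSE)
    cell_types[[j]] <- peak_set(peaks, factor = "CTCF", cell_type = cts[j],
                                dataset = paste0("CTCF.", cts[j]))
  }
  list(master = master, cell_types = cell_types, truth = truth,
       sizes = config$genome)
}

#' Simulate a co-binding factor peak set
#'
#' Plants `round(f * n_ctcf)` peaks within +/- 50 bp of distinct randomly
#' chosen CTCF summits and adds `n_extra` background peaks placed uniformly
#' while avoiding CTCF summits by more than 700 bp, so the planted fraction
#' `f` is the exact expected overlap ratio under 200 bp resizing.
#'
#' @param config a [sim_config()].
#' @param master master site table from [simulate_compendium()].
#' @param name factor name.
#' @param f planted co-binding fraction in `[0, 1]`.
#' @param n_extra number of background peaks.
#' @return A [peak_set()] with ground-truth columns `planted` (logical) and
#'   `site_index` (master-site row or `NA`).
#' @export
simulate_factor <- function(config, master, name, f, n_extra) {
  stopifnot(inherits(config, "sim_config"), f >= 0, f <= 1, n_extra >= 0)
  set.seed(.stream_seed(config$seed, paste0("factor:", name)))
  n_sites <- nrow(master)
  n_planted <- round(f * n_sites)
  idx <- if (n_planted) sort(sample.int(n_sites, n_planted)) else integer(0)
  master_summit <- master$start + master$summit   # absolute summit positions
  planted_summit <- master_summit[idx] + sample(-50:50, n_planted, replace = TRUE)
  planted <- data.frame(
    chrom = master$chrom[idx],
    summit_abs = planted_summit,
    planted = rep(TRUE, n_planted),
    site_index = idx, stringsAsFactors = FALSE)
  ## background: rejection-sample uniform summits > 700 bp from any CTCF summit
  bg <- NULL
  if (n_extra > 0) {
    genome <- config$genome
    need <- n_extra
    acc_chrom <- character(0); acc_pos <- integer(0)
    while (need > 0) {
      m <- max(2L * need, 100L)
      ch <- sample(names(genome), m, replace = TRUE,
                   prob = genome / sum(genome))
      pos <- as.integer(floor(runif(m, 700, unname(genome[ch]) - 700)))
      cand <- data.frame(chrom = ch, start = pos - 700L, end = pos + 700L)
      hit <- .count_ov(cand,
        data.frame(chrom = master$chrom, start = master_summit,
                   end = master_summit + 1L)) > 0L
      ok <- which(!hit)[seq_len(min(need, sum(!hit)))]
      acc_chrom <- c(acc_chrom, ch[ok]); acc_pos <- c(acc_pos, pos[ok])
      need <- n_extra - length(acc_pos)
    }
    bg <- data.frame(chrom = acc_chrom, summit_abs = acc_pos,
                     planted = FALSE, site_index = NA_integer_,
                     stringsAsFactors = FALSE)
  }
  all <- rbind(planted, bg)
  if (!nrow(all)) {
    return(peak_set(.empty_intervals(), factor = name, cell_type = "sim"))
  }
  all <- all[order(all$chrom, all$summit_abs), , drop = FALSE]
  peaks <- data.frame(
    chrom = all$chrom,
    start = as.integer(all$summit_abs - 150L),
    end = as.integer(all$summit_abs + 150L),
    name = paste0(name, "_peak_", seq_len(nrow(all))),
    signal = rlnorm(nrow(all), config$signal_meanlog, config$signal_sdlog),
    summit = 150L,
    planted = all$planted, site_index = all$site_index,
    stringsAsFactors = FALSE)
  peak_set(peaks, factor = name, cell_type = "sim",
           dataset = paste0(name, ".sim"))
}

#' Simulate CTCF-anchored loops with factor-dependent PET counts
#'
#' Anchors are master CTCF sites resized to `anchor_width` around the
#' summit; loop partners are drawn on the same chromosome within
#' `max_span`. PET counts follow 1 + Poisson(`pet_lambda`), multiplied by
#' `loop_boost` once for every promoting factor whose planted peaks bind
#' either anchor.
#'
#' @param config a [sim_config()].
#' @param master master site table from [simulate_compendium()].
#' @param factor_sets named list of [simulate_factor()] outputs (may be
#'   empty); only factors named in `loop_spec$promoting_factors` influence
#'   counts.
#' @return A [loop_set()] with ground-truth columns `site_a`, `site_b`
#'   (master-site indices), `boosted` and `n_boost_factors`.
#' @export
simulate_loops <- function(config, master, factor_sets = list()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config$seed, "loops"))
  ls <- config$loop_spec
  empty <- loop_set(data.frame(chrom1 = character(0), start1 = integer(0),
                               end1 = integer(0), chrom2 = character(0),
                               start2 = integer(0), end2 = integer(0)))
  if (ls$n_loops < 1) return(empty)
  half <- ls$anchor_width %/% 2L
  n_sites <- nrow(master)
  master_summit <- master$start + master$summit   # absolute summit positions
  ## per-promoting-factor planted site index sets
  boost_sites <- lapply(ls$promoting_factors, function(fn) {
    fs <- factor_sets[[fn]]
    if (is.null(fs)) integer(0) else unique(fs$site_index[fs$planted])
  })
  i <- sample.int(n_sites, ls$n_loops, replace = TRUE)
  ## partner: same chromosome, within max_span, distinct site
  j <- vapply(i, function(a) {
    cand <- which(master$chrom == master$chrom[a] &
                    abs(master_summit - master_summit[a]) <= ls$max_span)
    cand <- setdiff(cand, a)
    if (!length(cand)) a else cand[sample.int(length(cand), 1L)]
  }, integer(1))
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  a <- pmin(i, j); b <- pmax(i, j)
  base <- 1L + rpois(length(a), ls$pet_lambda)
  n_boost <- rep(0L, length(a))
  for (bs in boost_sites) {
    n_boost <- n_boost + as.integer(a %in% bs | b %in% bs)
  }
  pet <- as.integer(round(base * ls$loop_boost^n_boost))
  loops <- data.frame(
    chrom1 = master$chrom[a],
    start1 = as.integer(master_summit[a] - half),
    end1 = as.integer(master_summit[a] - half + ls$anchor_width),
    chrom2 = master$chrom[b],
    start2 = as.integer(master_summit[b] - half),
    end2 = as.integer(master_summit[b] - half + ls$anchor_width),
    name = paste0("loop_", seq_along(a)),
    pet_count = pet,
    site_a = a, site_b = b,
    boosted = n_boost > 0L, n_boost_factors = n_boost,
    stringsAsFactors = FALSE)
  loop_set(loops)
}

#' Simulate two-condition loop counts with planted fold changes
#'
#' Non-differential loops receive two Poisson draws of equal mean (the
#' loop's PET count); a planted fraction gets knockdown means shifted by
#' the configured fold, half decreased and half increased.
#'
#' @param loops a [loop_set()] (PET counts give the base means).
#' @param diff_spec list with `diff_fraction` and `fold`.
#' @param seed integer seed for this stream.
#' @return `loops` with columns `count_control`, `count_kd`,
#'   `diff_planted` (logical) and `diff_direction`
#'   (`"down_in_kd"`/`"up_in_kd"`/`NA`).
#' @export
simulate_conditions <- function(loops, diff_spec, seed = 1L) {
  stopifnot(inherits(loops, "loop_set") || is.data.frame(loops))
  set.seed(.stream_seed(seed, "conditions"))
  n <- nrow(loops)
  if (!n) {
    loops$count_control <- integer(0); loops$count_kd <- integer(0)
    loops$diff_planted <- logical(0); loops$diff_direction <- character(0)
    return(loops)
  }
  is_diff <- runif(n) < diff_spec$diff_fraction
  direction <- rep(NA_character_, n)
  direction[is_diff] <- sample(c("down_in_kd", "up_in_kd"),
                               sum(is_diff), replace = TRUE)
  m <- as.numeric(loops$pet_count)
  mean_kd <- m
  mean_kd[which(direction == "down_in_kd")] <-
    m[which(direction == "down_in_kd")] / diff_spec$fold
  mean_kd[which(direction == "up_in_kd")] <-
    m[which(direction == "up_in_kd")] * diff_spec$fold
  loops$count_control <- rpois(n, m)
  loops$count_kd <- rpois(n, mean_kd)
  loops$diff_planted <- is_diff
  loops$diff_direction <- direction
  loops
}

.state_names <- c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD", "Tx", "TxWk",
                  "EnhG1", "EnhG2", "EnhA1", "EnhA2", "EnhWk", "ZNF_Rpts",
                  "Het", "TssBiv", "EnhBiv", "ReprPC", "ReprPCWk", "Quies")

#' Simulate a chromatin-state segmentation and TSS/enhancer tracks
#'
#' Tiles each chromosome gaplessly with 18-state-style segments, places
#' TSS and enhancer elements on disjoint slots (so candidate promoters and
#' enhancers never collide), and marks an `active_fraction` of the
#' elements with an active-transcription interval contained in the
#' element.
#'
#' @param config a [sim_config()].
#' @return list with `states` (BED-like data.frame with `name` = state
#'   label), `tss` (single-base intervals), `enhancers`, `transcribed`
#'   (active-transcription intervals) and `truth` (per-element type and
#'   active flag).
#' @export
simulate_states_and_ep <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config$seed, "states"))
  genome <- config$genome
  ## gapless segmentation; quiescent-heavy state frequencies
  w <- c(1, 1, 0.5, 0.5, 2, 4, 0.7, 0.7, 1, 1, 2, 0.5, 1, 0.3, 0.5, 1, 2, 8)
  states <- do.call(rbind, lapply(names(genome), function(ch) {
    L <- unname(genome[ch])
    lens <- integer(0); tot <- 0
    while (tot < L) {
      add <- as.integer(200 + round(rexp(256, 1 / 10000)))
      lens <- c(lens, add); tot <- sum(lens)
    }
    cum <- cumsum(lens)
    k <- which(cum >= L)[1]
    lens <- lens[seq_len(k)]
    lens[k] <- lens[k] - (cum[k] - L)
    lab <- sample(.state_names, k, replace = TRUE, prob = w)
    data.frame(chrom = ch, start = c(0L, cumsum(lens)[-k]),
               end = cumsum(lens), name = lab, stringsAsFactors = FALSE)
  }))
  rownames(states) <- NULL
  es <- config$ep_spec
  n_el <- es$n_tss + es$n_enhancers
  ## one element per slot, alternating type assignment shuffled
  slot_tab <- do.call(rbind, lapply(names(genome), function(ch) {
    n <- round(n_el * unname(genome[ch]) / sum(genome))
    data.frame(chrom = ch, slot = seq_len(n),
               slot_width = floor(unname(genome[ch]) / n),
               stringsAsFactors = FALSE)
  }))
  slot_tab <- slot_tab[seq_len(min(n_el, nrow(slot_tab))), , drop = FALSE]
  n_el <- nrow(slot_tab)
  margin <- 2000L
  pos <- as.integer((slot_tab$slot - 1) * slot_tab$slot_width + margin +
                      floor(runif(n_el) * pmax(slot_tab$slot_width - 2 * margin, 1)))
  type <- sample(rep(c("tss", "enhancer"),
                     c(es$n_tss, n_el - es$n_tss))[seq_len(n_el)])
  active <- runif(n_el) < es$active_fraction
  ids <- ifelse(type == "tss",
                paste0("tss_", cumsum(type == "tss")),
                paste0("enh_", cumsum(type == "enhancer")))
  enh_half <- as.integer(floor(runif(n_el, 250, 750)))
  truth <- data.frame(id = ids, chrom = slot_tab$chrom, pos = pos,
                      type = type, active = active, stringsAsFactors = FALSE)
  tss <- data.frame(chrom = slot_tab$chrom[type == "tss"],
                    start = pos[type == "tss"],
                    end = pos[type == "tss"] + 1L,
                    name = ids[type == "tss"], stringsAsFactors = FALSE)
  enh <- data.frame(chrom = slot_tab$chrom[type == "enhancer"],
                    start = pos[type == "enhancer"] - enh_half[type == "enhancer"],
                    end = pos[type == "enhancer"] + enh_half[type == "enhancer"],
                    name = ids[type == "enhancer"], stringsAsFactors = FALSE)
  ## active-transcription interval: 200 bp centered in the element
  transcribed <- data.frame(chrom = slot_tab$chrom[active],
                            start = pos[active] - 100L,
                            end = pos[active] + 100L,
                            name = paste0("txn_", seq_len(sum(active))),
                            stringsAsFactors = FALSE)
  lapply(list(states, tss, enh), .check_intervals)
  list(states = states, tss = tss, enhancers = enh,
       transcribed = transcribed, truth = truth)
}

#' Run the full simulation
#'
#' Convenience wrapper running every generator stage off one configuration.
#'
#' @param config a [sim_config()].
#' @return list with `compendium`, `factors` (named list of peak sets),
#'   `loops`, `loops_conditions`, `ep` and the `config`.
#' @export
simulate_all <- function(config = sim_config()) {
  comp <- simulate_compendium(config)
  factors <- setNames(
    lapply(config$factor_specs, function(fs) {
      simulate_factor(config, comp$master, fs$name, fs$f, fs$n_extra)
    }),
    vapply(config$factor_specs, `[[`, character(1), "name"))
  loops <- simulate_loops(config, comp$master, factors)
  loops_cond <- simulate_conditions(loops, config$diff_spec, config$seed)
  ep <- simulate_states_and_ep(config)
  list(compendium = comp, factors = factors, loops = loops,
       loops_conditions = loops_cond, ep = ep, config = config)
}

#' Write a simulation to disk
#'
#' Emits narrowPeak files per cell type and factor, BED files for master
#' sites, states, TSS, enhancers and transcribed intervals, BEDPE loop
#' files, and tab-separated truth tables. Identical configurations produce
#' byte-identical files.
#'
#' @param sim output of [simulate_all()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_bed(sim$compendium$master, fp("ctcf_master.bed"))
  for (ct in names(sim$compendium$cell_types)) {
    write_narrowpeak(sim$compendium$cell_types[[ct]],
                     fp(paste0("ctcf_", ct, ".narrowPeak")))
  }
  for (fn in names(sim$factors)) {
    write_narrowpeak(sim$factors[[fn]], fp(paste0("factor_", fn, ".narrowPeak")))
  }
  write_bedpe_loops(sim$loops, fp("loops.bedpe"))
  write_bedpe_loops(sim$loops_conditions, fp("loops_conditions.bedpe"))
  write_bed(sim$ep$states, fp("states.bed"))
  write_bed(sim$ep$tss, fp("tss.bed"))
  write_bed(sim$ep$enhancers, fp("enhancers.bed"))
  write_bed(sim$ep$transcribed, fp("transcribed.bed"))
  tt <- function(x, f) write.table(x, fp(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  tt(data.frame(site = rownames(sim$compendium$truth),
                sim$compendium$truth), "truth_presence.tsv")
  tt(sim$ep$truth, "truth_elements.tsv")
  tt(as.data.frame(sim$loops)[, c("name", "site_a", "site_b", "boosted",
                                  "n_boost_factors")], "truth_loops.tsv")
  invisible(dir)
}
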