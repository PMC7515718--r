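mk_loops <- function(chrom1, start1, chrom2, start2, width = 500L,
                     pet = 1L, ...) {
  loop_set(data.frame(chrom1 = chrom1, start1 = start1,
                      end1 = start1 + width, chrom2 = chrom2,
                      start2 = start2, end2 = start2 + width,
                      pet_count = pet, ..., stringsAsFactors = FALSE))
}

test_that("assign_unique_ctcf keeps anchors with exactly one CTCF peak", {
  anchors <- data.frame(chrom = "chr1",
                        start = c(0, 10000, 20000),
                        end = c(1000, 11000, 21000))
  # anchor 1: two peaks; anchor 2: one; anchor 3: none
  ctcf <- mk_peaks("chr1", c(100, 600, 10100), c(300, 800, 10300),
                   summit = 100, factor = "CTCF")
  expect_message(out <- assign_unique_ctcf(anchors, ctcf), "dropped 1")
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 10000)
  expect_equal(out$ctcf_index, 3L)
  expect_equal(attr(out, "n_dropped_zero"), 1L)
  expect_equal(attr(out, "n_dropped_multi"), 1L)
})

test_that("assign_unique_ctcf matches the brute-force per-anchor count", {
  set.seed(61)
  for (i in 1:10) {
    anchors <- rand_intervals(80)
    ctcf <- peak_set(rand_peaks(60), factor = "CTCF")
    out <- suppressMessages(assign_unique_ctcf(anchors, ctcf))
    expected <- vapply(seq_len(nrow(anchors)), function(j) {
      sum(anchors$chrom[j] == ctcf$chrom &
            anchors$start[j] < ctcf$end & ctcf$start < anchors$end[j]) == 1L
    }, logical(1))
    expect_equal(nrow(out), sum(expected))
  }
})

test_that("anchor_loop_strength sums PET counts over mediated loops", {
  anchors <- data.frame(chrom = "chr1", start = c(0, 10000, 50000),
                        end = c(500, 10500, 50500))
  loops <- mk_loops("chr1", c(0, 0), "chr1", c(10000, 20000), pet = c(3L, 5L))
  out <- anchor_loop_strength(anchors, loops)
  expect_equal(out$loop_strength, c(8, 3, 0))
  # self-looping anchor counts once per end
  self <- mk_loops("chr1", 0, "chr1", 100, pet = 7L)
  expect_equal(anchor_loop_strength(anchors[1, ], self)$loop_strength, 14)
})

test_that("total anchor strength satisfies the conservation law", {
  set.seed(62)
  for (i in 1:10) {
    anchors <- rand_intervals(60)
    n <- 80
    a <- rand_intervals(n); b <- rand_intervals(n)
    loops <- loop_set(data.frame(
      chrom1 = a$chrom, start1 = a$start, end1 = a$end,
      chrom2 = b$chrom, start2 = b$start, end2 = b$end,
      pet_count = sample.int(20, n, replace = TRUE)))
    out <- anchor_loop_strength(anchors, loops)
    ends_hit <- vapply(seq_len(n), function(l) {
      ha <- sum(loops$chrom1[l] == anchors$chrom &
                  loops$start1[l] < anchors$end & anchors$start < loops$end1[l])
      hb <- sum(loops$chrom2[l] == anchors$chrom &
                  loops$start2[l] < anchors$end & anchors$start < loops$end2[l])
      ha + hb
    }, numeric(1))
    expect_equal(sum(out$loop_strength), sum(loops$pet_count * ends_hit))
  }
})

test_that("cobinding_strength_test separates planted strata and respects the gate", {
  # full separation: co-bound anchors all strong
  n <- 50
  anchors <- data.frame(chrom = "chr1",
                        start = seq(0, by = 10000, length.out = 2 * n))
  anchors$end <- anchors$start + 500
  anchors$ctcf_start <- anchors$start
  anchors$ctcf_end <- anchors$start + 400
  anchors$ctcf_summit <- 200L
  anchors$loop_strength <- rep(c(100, 1), each = n)
  fac <- peak_set(data.frame(chrom = "chr1", start = anchors$start[1:n],
                             end = anchors$start[1:n] + 400, summit = 200L),
                  factor = "X")
  out <- cobinding_strength_test(anchors, fac, n_factors_tested = 100)
  expect_lt(out$p, 1e-15)
  expect_gte(out$neg_log10_fdr, 20)
  expect_true(out$passes_screen)
  expect_equal(out$fdr, min(1, out$p * 100))

  # identical strata: one-sided p ~ 1-ish, never passes
  anchors$loop_strength <- rep(5, 2 * n)
  out2 <- cobinding_strength_test(anchors, fac)
  expect_gt(out2$p, 0.4)
  expect_false(out2$passes_screen)

  # empty stratum: untestable
  none <- peak_set(data.frame(chrom = "chr9", start = 0, end = 100),
                   factor = "Y")
  out3 <- cobinding_strength_test(anchors, none)
  expect_false(out3$testable)
  expect_false(out3$passes_screen)
})

test_that("cobinding test is invariant under monotone strength transforms", {
  set.seed(63)
  n <- 60
  anchors <- data.frame(chrom = "chr1",
                        start = seq(0, by = 10000, length.out = n))
  anchors$end <- anchors$start + 500
  anchors$ctcf_start <- anchors$start; anchors$ctcf_end <- anchors$start + 400
  anchors$ctcf_summit <- 200L
  anchors$loop_strength <- rexp(n, 0.1)
  cob <- sample(n, 25)
  fac <- peak_set(data.frame(chrom = "chr1", start = anchors$start[cob],
                             end = anchors$start[cob] + 400, summit = 200L),
                  factor = "X")
  p1 <- cobinding_strength_test(anchors, fac)$p
  anchors$loop_strength <- log1p(anchors$loop_strength) * 7 + 2
  p2 <- cobinding_strength_test(anchors, fac)$p
  expect_equal(p1, p2)
})

test_that("normalize_binding implements the log2 length normalization", {
  expect_equal(normalize_binding(1, 1000), 0)
  expect_equal(normalize_binding(1000, 1000), log2(1000))
  expect_equal(normalize_binding(0, 500), 1)   # +1 pseudocount on zero
  expect_error(normalize_binding(-1, 100))
})

test_that("state_category applies the collapse map, max-overlap and priority rules", {
  seg <- data.frame(chrom = "chr1",
                    start = c(0, 1000, 2000, 3000),
                    end = c(1000, 2000, 3000, 10000),
                    name = c("TssA", "EnhA1", "Tx", "Quies"))
  sites <- data.frame(chrom = "chr1",
                      start = c(100, 1400, 2900),
                      end = c(300, 2400, 3200))
  # fully inside TssA; 60% EnhA1/40% Tx; 100 Tx vs 200 Quies
  expect_equal(state_category(sites, seg),
               c("promoter", "enhancer", "quies"))
  # exact tie goes to the higher-priority category
  tie <- data.frame(chrom = "chr1", start = 1500, end = 2500)
  expect_equal(state_category(tie, seg), "enhancer")
})

test_that("state_category agrees with the per-base oracle on random tilings", {
  set.seed(64)
  for (i in 1:10) {
    bounds <- sort(sample(1000:99000, 30))
    seg <- data.frame(chrom = "chrA", start = c(0, bounds),
                      end = c(bounds, 1e5),
                      name = sample(c("TssA", "EnhA1", "Tx", "ReprPCWk",
                                      "Quies", "Het", "TxWk", "EnhWk"),
                                    31, replace = TRUE))
    sites <- rand_intervals(50, chroms = "chrA")
    expect_equal(state_category(sites, seg), oracle_state_category(sites, seg))
  }
})

test_that("stratified_correlation recovers planted relations and gates unreliable strata", {
  set.seed(65)
  n <- 2000
  x <- rnorm(n, 5, 1)
  strength <- 2^(2 * x + rnorm(n, 0, 0.5))   # log2 strength = 2x + eps
  cat5 <- rep("promoter", n)
  out <- stratified_correlation(x, strength, cat5, n_tests = 5)
  r_pop <- 2 / sqrt(4 + 0.25)      # population Pearson r
  se_r <- (1 - r_pop^2) / sqrt(n - 3)
  expect_lt(abs(out$r - r_pop), 3 * se_r)
  expect_gt(out$reported_score, 0)

  # stratum below the n gate: score exactly 0 regardless of r
  out2 <- stratified_correlation(x[1:500], strength[1:500],
                                 rep("enhancer", 500), n_tests = 5)
  expect_identical(out2$reported_score, 0)
  # independent data: p-gate fires
  out3 <- stratified_correlation(rnorm(n), 2^rnorm(n), cat5, n_tests = 5)
  expect_true(out3$reported_score == 0 || out3$p <= 0.01)
})

test_that("differential_loops applies the printed rule exactly", {
  loops <- data.frame(count_control = c(3, 1, 4, 0),
                      count_kd = c(0, 1, 2, 9))
  out <- differential_loops(loops)
  expect_equal(attr(out, "n_filtered"), 1L)   # (1,1) max < 2
  expect_equal(out$fold_change, c(4, 5 / 3, 1 / 10))
  expect_equal(out$differential, c(TRUE, FALSE, TRUE))
  expect_equal(out$direction, c("down_in_kd", "stable", "up_in_kd"))
  # symmetry: swapping the condition columns swaps directions only
  sw <- differential_loops(data.frame(count_control = loops$count_kd,
                                      count_kd = loops$count_control))
  expect_equal(sw$differential, out$differential)
  expect_equal(sw$direction == "down_in_kd", out$direction == "up_in_kd")
})

test_that("strength_change_by_binding_change bins anchors and tests pairs", {
  set.seed(66)
  n <- 500
  b <- rnorm(n, 0, 1)
  s <- b + rnorm(n, 0, 0.3)        # planted coupling
  out <- strength_change_by_binding_change(b, s)
  expect_equal(sum(out$bins$n), n)
  meds <- out$bins$median_strength_l2fc
  expect_true(all(diff(meds[!is.na(meds)]) > 0))  # monotone bin medians
  expect_gt(nrow(out$tests), 0)
  # single occupied bin: warning, no tests
  expect_warning(out1 <- strength_change_by_binding_change(rep(0, 10),
                                                           rnorm(10)),
                 "one occupied")
  expect_equal(nrow(out1$tests), 0L)
})
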