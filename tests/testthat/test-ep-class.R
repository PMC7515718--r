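rand_loops <- function(n, chrom = "chr1", span = 2e5, width = 1e4) {
  s1 <- sample.int(span, n, replace = TRUE)
  gap <- sample.int(span, n, replace = TRUE) + width
  data.frame(chrom1 = chrom, start1 = s1, end1 = s1 + width,
             chrom2 = chrom, start2 = s1 + gap, end2 = s1 + gap + width,
             stringsAsFactors = FALSE)
}

test_that("candidate_promoters flanks TSS and clips at boundaries", {
  tss <- data.frame(chrom = "chr1", start = c(10000, 200),
                    name = c("t1", "t2"))
  out <- candidate_promoters(tss, 500, sizes = c(chr1 = 1e6))
  expect_equal(out$start, c(9500, 0))
  expect_equal(out$end, c(10500, 700))
  expect_equal(nrow(out), nrow(tss))
  expect_error(candidate_promoters(data.frame(chrom = "chrX", start = 1),
                                   sizes = c(chr1 = 1e6)), "chrX")
})

test_that("active_elements keeps candidates intersecting transcription", {
  cands <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                      end = c(500, 1500, 2500))
  genome_wide <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  expect_equal(nrow(active_elements(cands, genome_wide)), 3L)
  expect_equal(nrow(active_elements(cands, genome_wide[integer(0), ])), 0L)
  tx <- data.frame(chrom = "chr1", start = 1200, end = 1300)
  expect_equal(active_elements(cands, tx)$start, 1000)
})

test_that("extract_ep_loops expands anchor element combinations", {
  loops <- loop_set(data.frame(chrom1 = "chr1", start1 = 0, end1 = 10000,
                               chrom2 = "chr1", start2 = 50000, end2 = 60000))
  enh <- data.frame(chrom = "chr1", start = c(1000, 5000), end = c(1500, 5500),
                    name = c("e1", "e2"))
  prom <- data.frame(chrom = "chr1", start = c(51000, 53000, 55000),
                     end = c(52000, 54000, 56000),
                     name = c("p1", "p2", "p3"))
  ep <- extract_ep_loops(loops, prom, enh)
  expect_equal(nrow(ep), 6L)      # 2 enhancers x 3 promoters
  expect_setequal(unique(ep$enhancer_id), c("e1", "e2"))
  # no promoter on either anchor -> nothing
  expect_equal(nrow(extract_ep_loops(loops, prom[integer(0), ], enh)), 0L)
  # E and P on the same anchor only -> does not qualify
  same_side <- loop_set(data.frame(chrom1 = "chr1", start1 = 0, end1 = 10000,
                                   chrom2 = "chr1", start2 = 9e5, end2 = 9.1e5))
  enh2 <- data.frame(chrom = "chr1", start = 100, end = 200, name = "e")
  prom2 <- data.frame(chrom = "chr1", start = 300, end = 400, name = "p")
  expect_equal(nrow(extract_ep_loops(same_side, prom2, enh2)), 0L)
})

test_that("extract_ep_loops matches a brute-force annotation oracle", {
  set.seed(81)
  for (rep in 1:5) {
    loops <- loop_set(rand_loops(40))
    enh <- rand_intervals(30, chroms = "chr1", chrom_len = 5e5)
    enh$name <- paste0("e", seq_len(nrow(enh)))
    prom <- rand_intervals(30, chroms = "chr1", chrom_len = 5e5)
    prom$name <- paste0("p", seq_len(nrow(prom)))
    ep <- extract_ep_loops(loops, prom, enh)
    ovl <- function(iv, els) which(vapply(seq_len(nrow(els)), function(j) {
      iv$start < els$end[j] & els$start[j] < iv$end
    }, logical(1)))
    n_expected <- 0L
    for (l in seq_len(nrow(loops))) {
      A <- loops[l, c("start1", "end1")]; names(A) <- c("start", "end")
      B <- loops[l, c("start2", "end2")]; names(B) <- c("start", "end")
      n_expected <- n_expected +
        length(ovl(A, enh)) * length(ovl(B, prom)) +
        length(ovl(B, enh)) * length(ovl(A, prom))
    }
    expect_equal(nrow(ep), n_expected)
  }
})

test_that("classify_relation implements the five categories with fixed precedence", {
  ctcf <- data.frame(chrom1 = "chr1", start1 = 0, end1 = 10000,
                     chrom2 = "chr1", start2 = 100000, end2 = 110000)
  # identical anchors -> category 4
  expect_equal(classify_relation(ctcf, ctcf), 4L)
  # EP nested strictly inside the CTCF span -> 1
  ep1 <- data.frame(chrom1 = "chr1", start1 = 30000, end1 = 40000,
                    chrom2 = "chr1", start2 = 60000, end2 = 70000)
  expect_equal(classify_relation(ctcf, ep1), 1L)
  # role exchange maps 1 -> 2
  expect_equal(classify_relation(ep1, ctcf), 2L)
  # crossing spans, no containment, no reciprocal anchors -> 3
  ctcf3 <- data.frame(chrom1 = "chr1", start1 = 0, end1 = 10000,
                      chrom2 = "chr1", start2 = 40000, end2 = 50000)
  ep3 <- data.frame(chrom1 = "chr1", start1 = 42000, end1 = 43000,
                    chrom2 = "chr1", start2 = 80000, end2 = 90000)
  expect_equal(classify_relation(ctcf3, ep3), 3L)
  expect_equal(classify_relation(ep3, ctcf3), 3L)
  # disjoint spans -> 5; cross-chromosome -> 5
  ep5 <- data.frame(chrom1 = "chr1", start1 = 300000, end1 = 310000,
                    chrom2 = "chr1", start2 = 400000, end2 = 410000)
  expect_equal(classify_relation(ctcf, ep5), 5L)
  ep5b <- ep1; ep5b$chrom1 <- ep5b$chrom2 <- "chr2"
  expect_equal(classify_relation(ctcf, ep5b), 5L)
  # reciprocal anchor overlap wins over containment -> 4
  ep4 <- data.frame(chrom1 = "chr1", start1 = 500, end1 = 9000,
                    chrom2 = "chr1", start2 = 100500, end2 = 109000)
  expect_equal(classify_relation(ctcf, ep4), 4L)
})

test_that("classification is total, single-valued and respects its symmetries", {
  set.seed(82)
  n <- 2000
  ctcf <- rand_loops(n)
  ep <- rand_loops(n)
  cat_fwd <- classify_relation(ctcf, ep)
  expect_true(all(cat_fwd %in% 1:5))
  expect_length(cat_fwd, n)
  # anchor-swap invariance (either loop)
  swap <- function(x) {
    y <- x
    y[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")] <-
      x[, c("chrom2", "start2", "end2", "chrom1", "start1", "end1")]
    y
  }
  expect_equal(classify_relation(swap(ctcf), ep), cat_fwd)
  expect_equal(classify_relation(ctcf, swap(ep)), cat_fwd)
  # role exchange: 1 <-> 2, fixes 3, 4, 5
  cat_rev <- classify_relation(ep, ctcf)
  expect_equal(cat_rev == 1, cat_fwd == 2)
  expect_equal(cat_rev == 2, cat_fwd == 1)
  expect_equal(cat_rev[cat_fwd %in% 3:5], cat_fwd[cat_fwd %in% 3:5])
  # identical loops always category 4
  expect_true(all(classify_relation(ctcf, ctcf) == 4L))
})

test_that("relation_table and relation_summary recount consistently", {
  set.seed(83)
  ctcf <- loop_set(rand_loops(5))
  # loops anchored exactly on the element grid so extraction always succeeds
  s1 <- seq(0, 90000, by = 10000); s2 <- seq(100000, 190000, by = 10000)
  src <- loop_set(data.frame(chrom1 = "chr1", start1 = s1, end1 = s1 + 10000,
                             chrom2 = "chr1", start2 = s2, end2 = s2 + 10000))
  ep <- extract_ep_loops(
    src,
    data.frame(chrom = "chr1", start = seq(101000, 191000, by = 10000),
               end = seq(102000, 192000, by = 10000)),
    data.frame(chrom = "chr1", start = seq(5000, 95000, by = 10000),
               end = seq(6000, 96000, by = 10000)))
  expect_gt(nrow(ep), 0)
  rt <- relation_table(ctcf, ep)
  expect_equal(nrow(rt), nrow(ctcf) * nrow(ep))
  rs <- relation_summary(rt)
  expect_equal(sum(rs$counts), nrow(rt))
  expect_equal(as.integer(rs$counts["4"]), sum(rt$category == 4))
  # per-loop rollup covers every category the loop participates in
  one <- rs$per_ctcf_loop[1, ]
  expect_equal(one$categories[[1]],
               sort(unique(rt$category[rt$ctcf_loop_id == one$ctcf_loop_id])))
  # disjoint loop sets: all category 5
  far <- loop_set(data.frame(chrom1 = "chr9", start1 = 0, end1 = 100,
                             chrom2 = "chr9", start2 = 5000, end2 = 5100))
  expect_true(all(relation_table(far, ep)$category == 5L))
})
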