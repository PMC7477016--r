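mk_ihs <- function(pos, abs_ihs, chrom = "1")
  data.frame(chrom = chrom, pos = pos, abs_ihs = abs_ihs,
             ihs = abs_ihs, p_derived = 0.5)

test_that("iHS window binning follows the hand-enumerated toy", {
  # bins: (25 SNPs, 10 extreme), (30, 3), (19, 19) -> third excluded
  pos <- c(seq(1, 25) * 1000,                 # bin [0, 100kb)
           100000 + seq(1, 30) * 1000,        # bin [100kb, 200kb)
           200000 + seq(1, 19) * 1000)        # bin [200kb, 300kb)
  scores <- c(rep(3, 10), rep(0.5, 15), rep(3, 3), rep(0.1, 27), rep(4, 19))
  w <- bin_ihs(mk_ihs(pos, scores), min_snps = 20)
  expect_equal(w$n_snps, c(25L, 30L, 19L))
  expect_equal(w$n_extreme, c(10L, 3L, 19L))
  expect_equal(w$fraction[1:2], c(0.40, 0.10))
  expect_equal(w$included, c(TRUE, TRUE, FALSE))
  expect_equal(w$significant, c(TRUE, FALSE, FALSE))
  # an excluded bin is never significant however extreme its fraction
  expect_false(w$significant[3])
})

test_that("window counting is invariant to record order and all-null scans stay empty", {
  pos <- sort(sample.int(3e5, 90))
  sc <- stats::runif(90, 0, 1.5)   # nothing above the threshold
  w <- bin_ihs(mk_ihs(pos, sc), min_snps = 10)
  expect_true(all(w$fraction[w$included] == 0))
  expect_false(any(w$significant))
  ord <- sample(90)
  w2 <- bin_ihs(mk_ihs(pos[ord], sc[ord]), min_snps = 10)
  expect_equal(w2$n_snps, w$n_snps)
  expect_equal(w2$n_extreme, w$n_extreme)
})

test_that("gene annotation assigns by overlap for windows and by flank for peaks", {
  toy <- make_toy_fixtures()$genes
  # window overlap, half-open
  hit <- annotate_genes(data.frame(chrom = "1", start = 100000L, end = 200000L),
                        data.frame(chrom = "1", start = 150000L,
                                   end = 160000L, name = "g"))
  expect_equal(hit$gene, "g")
  # peak flank boundary: 100001 bp beyond is out, 100000 is in
  peak <- data.frame(chrom = "1", pos = 1000L)
  g_out <- data.frame(chrom = "1", start = 999L + 100001L,
                      end = 999L + 100001L + 10L, name = "far")
  expect_equal(nrow(annotate_genes(peak, g_out, flank_bp = 100000)), 0L)
  g_in <- data.frame(chrom = "1", start = 999L + 100000L,
                     end = 999L + 100000L + 10L, name = "edge")
  expect_equal(annotate_genes(peak, g_in, flank_bp = 100000)$gene, "edge")
  # 5-gene / 3-window toy matches the manual intersection
  ann <- annotate_genes(toy$windows, toy$genes)
  expect_equal(ann$start, c(0L, 0L, 100000L, 100000L, 200000L, 200000L))
  expect_equal(ann$gene, c("g1", "g2", "g3", "g4", "g4", "g5"))
})

test_that("differential candidate windows require signal in A absent from B", {
  posA <- sort(sample.int(1e5, 60))
  ihs_a <- mk_ihs(posA, c(rep(3, 21), rep(0.2, 39)))
  ihs_b0 <- mk_ihs(posA, rep(0.2, 60))          # B silent
  res <- candidate_sites(ihs_a, ihs_b0, min_extreme = 20)
  expect_equal(nrow(res$windows), 1L)
  expect_equal(res$windows$n_extreme, 21L)
  expect_equal(nrow(res$sites), 21L)
  # same window passing in B -> removed at step 2
  ihs_b1 <- mk_ihs(posA, c(rep(3, 25), rep(0.2, 35)))
  res2 <- candidate_sites(ihs_a, ihs_b1, min_extreme = 20)
  expect_equal(nrow(res2$windows), 0L)
  # strictly-greater-than-20 semantics
  ihs_a20 <- mk_ihs(posA, c(rep(3, 20), rep(0.2, 40)))
  expect_equal(nrow(candidate_sites(ihs_a20, ihs_b0, min_extreme = 20)$windows), 0L)
  # fixation filter on the selected-allele frequencies
  fa <- stats::setNames(rep(1.0, 60), paste("1", posA))
  fb <- stats::setNames(rep(0.6, 60), paste("1", posA))
  res3 <- candidate_sites(ihs_a, ihs_b0, min_extreme = 20,
                          freq_a = fa, freq_b = fb, fix_thresh = 0.95)
  expect_equal(nrow(res3$sites), 21L)
  res4 <- candidate_sites(ihs_a, ihs_b0, min_extreme = 20,
                          freq_a = fa * 0.9, freq_b = fb, fix_thresh = 0.95)
  expect_equal(nrow(res4$sites), 0L)
})

test_that("gene ranking gates then sums best-first ranks with average ties", {
  ev <- data.frame(gene = c("x", "y", "z"), chrom = "1",
                   start = c(0L, 100L, 200L), end = c(50L, 150L, 250L),
                   tajima_mean = c(2, 1, 0), fst_mean = c(0.06, 0.05, 0.04),
                   xpehh_max = c(4, 3, 2.6))
  rk <- rank_genes(ev, fst_quantile = 0, xpehh_min = 2.5)
  expect_equal(rk$gene, c("x", "y", "z"))
  expect_equal(rk$rank_score, c(3, 6, 9))
  # identical metrics -> equal scores through average ranks
  ev2 <- ev
  ev2[, c("tajima_mean", "fst_mean", "xpehh_max")] <-
    list(c(1, 1, 1), c(0.05, 0.05, 0.05), c(3, 3, 3))
  rk2 <- rank_genes(ev2, fst_quantile = 0, xpehh_min = 2.5)
  expect_true(all(rk2$rank_score == 6))
  # the xpEHH gate is strict
  ev3 <- ev; ev3$xpehh_max <- c(4, 2.5, 2.4)
  expect_equal(rank_genes(ev3, fst_quantile = 0)$gene, "x")
  # default gates match the published thresholds
  expect_equal(formals(rank_genes)$fst_quantile, 0.95)
  expect_equal(formals(rank_genes)$xpehh_min, 2.5)
})

test_that("evidence interval intersection is the sweep-line result", {
  A <- data.frame(chrom = "1", start = 0L, end = 100L)
  B <- data.frame(chrom = "1", start = 50L, end = 150L)
  got <- intersect_evidence(list(ihs = A, xpehh = B))
  expect_equal(got[, c("start", "end")], data.frame(start = 50L, end = 100L))
  # disjoint -> empty
  expect_equal(nrow(intersect_evidence(list(
    a = A, b = data.frame(chrom = "1", start = 200L, end = 300L)))), 0L)
  # three-collection toy against the manual sweep-line answer
  C1 <- data.frame(chrom = "1", start = c(0L, 200L), end = c(120L, 300L))
  C2 <- data.frame(chrom = "1", start = c(50L, 250L), end = c(260L, 290L))
  C3 <- data.frame(chrom = "1", start = 100L, end = 280L)
  # pairwise-fragment semantics: overlapping fragments are kept unmerged
  got3 <- intersect_evidence(list(a = C1, b = C2, c = C3))
  expect_equal(got3$start, c(100L, 200L, 250L))
  expect_equal(got3$end, c(120L, 260L, 280L))
})

test_that("per-gene evidence aggregates means, maxima and ratio-of-sums F_ST", {
  genes <- data.frame(chrom = "1", start = 0L, end = 1000L, name = "g")
  ihs <- mk_ihs(c(100L, 200L, 300L), c(3, 1, 2.5))
  xp <- data.frame(chrom = "1", pos = c(100L, 250L), xpehh = c(1.5, 2.9))
  td <- data.frame(chrom = "1", start = c(0L, 3000L), end = c(3000L, 6000L),
                   D = c(1.2, -4))
  fst <- data.frame(chrom = "1", pos = c(100L, 200L),
                    a = c(1, 0), b = c(1, 1), c = c(0, 0))
  ev <- gene_evidence(genes, ihs, xp, td, fst)
  expect_equal(ev$ihs_max, 3)
  expect_equal(ev$ihs_mean, mean(c(3, 1, 2.5)))
  expect_equal(ev$n_extreme, 2L)
  expect_equal(ev$freq_extreme, 2 / 3)
  expect_equal(ev$tajima_mean, 1.2)   # only the overlapping 3 kb bin
  expect_equal(ev$fst_mean, 1 / 3)
  expect_equal(ev$xpehh_max, 2.9)
})
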