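test_that("Hardy-Weinberg exact p matches exhaustive enumeration", {
  expect_equal(hwe_exact_test(5, 0, 0), 1.0)
  expect_equal(hwe_exact_test(1, 0, 1), oracle_hwe(1, 0, 1), tolerance = 1e-12)
  expect_equal(hwe_exact_test(50, 21, 29), oracle_hwe(50, 21, 29),
               tolerance = 1e-12)
  # randomized configurations up to n = 30
  set.seed(42)
  for (k in 1:200) {
    n <- sample(1:30, 1)
    cnt <- as.vector(stats::rmultinom(1, n, stats::runif(3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("site_stats counts alleles, missingness and frequencies directly", {
  gm <- rbind(c(0L, 2L, NA), c(0L, 2L, 0L), c(1L, 2L, 0L))
  rownames(gm) <- c("a", "b", "c")
  ss <- site_stats(gm)
  expect_equal(ss$maf[1], 1 / 6)
  expect_equal(ss$mac[1], 1L)
  expect_equal(ss$maf[2], 0)       # all homozygous alt
  expect_equal(ss$call_rate[3], 2 / 3)
  expect_equal(ss$n_called, c(3L, 3L, 2L))
})

test_that("LD pruning removes duplicates, keeps independents, is idempotent", {
  set.seed(7)
  n <- 200
  base <- matrix(rbinom(n * 10, 2, 0.4), n, 10)
  gm <- cbind(base[, 1], base[, 1], base[, 2:10])  # duplicated first column
  kept <- ld_prune(gm, r2_max = 0.1, window_snps = 10, step_snps = 2)
  expect_false(all(c(1, 2) %in% kept))  # exactly one of the duplicates
  expect_true(1 %in% kept)              # the earlier-position one
  # independent random columns stay (r^2 well below 0.1 at n = 200 is typical)
  expect_gte(length(kept), 9)
  # post-hoc: no kept pair within a window reaches the ceiling
  imp <- gm[, kept, drop = FALSE]
  for (w0 in seq(1, length(kept) - 1, by = 2)) {
    win <- w0:min(w0 + 9, length(kept))
    cc <- suppressWarnings(stats::cor(imp[, win]))
    cc[is.na(cc)] <- 0
    diag(cc) <- 0
    expect_lt(max(cc^2), 0.1)
  }
  expect_identical(ld_prune(gm[, kept, drop = FALSE], 0.1, 10, 2),
                   seq_along(kept))
  expect_error(ld_prune(gm, window_snps = 1), "window_snps")
})

test_that("filter cascade removes the toy's sites step by step as designed", {
  toy <- make_toy_fixtures()$qc
  res <- apply_filter_cascade(toy, stage = "scan")
  expect_equal(res$report$step,
               c("site_missingness", "minor_allele_count", "maf", "hwe",
                 "individual_missingness", "scan_maf"))
  expect_equal(res$report$removed, c(2L, 3L, 0L, 1L, 0L, 0L))
  expect_equal(nrow(res$cohort$sites), 4L)
  expect_equal(res$cohort$sites$pos, c(7000L, 8000L, 9000L, 10000L))
  # removals and survivors reconcile at every step
  expect_equal(res$report$remaining[4], 10L - sum(res$report$removed[1:4]))
})

test_that("slack thresholds leave the cohort untouched", {
  toy <- make_toy_fixtures()$qc
  cfg <- filter_config(max_site_missing = 1, min_minor_allele_count = 0,
                       min_maf = 0, hwe_p_min = 0, max_indiv_missing = 1,
                       scan_maf_min = 0)
  res <- apply_filter_cascade(toy, cfg, stage = "scan")
  expect_equal(sum(res$report$removed), 0L)
  expect_identical(res$cohort$geno, toy$geno)
})

test_that("default thresholds are the published filtering parameters", {
  cfg <- filter_config()
  expect_equal(cfg$max_site_missing, 0.10)
  expect_equal(cfg$min_minor_allele_count, 3L)
  expect_equal(cfg$min_maf, 0.01)
  expect_equal(cfg$hwe_p_min, 0.001)
  expect_equal(cfg$max_indiv_missing, 0.10)
  expect_equal(cfg$ld_r2_max, 0.1)
  expect_equal(cfg$scan_maf_min, 0.05)
})

test_that("per-population Hardy-Weinberg removal flags sites failing in any population", {
  # population P fails HWE badly (20 heterozygotes), population Q is clean
  g <- rbind(matrix(1L, 20, 1),
             matrix(rep(c(0L, 1L, 1L, 2L), length.out = 20), 20, 1))
  g <- cbind(g, rep(c(0L, 1L, 0L, 1L, 2L), 8))
  rownames(g) <- sprintf("s%02d", 1:40)
  co <- structure(list(
    sites = data.frame(chrom = "1", pos = c(100L, 200L), id = NA, ref = "A",
                       alt = "G", ancestral = "A", aa_fallback = FALSE),
    geno = g, haplo = NULL, samples = rownames(g), n_dropped = 0L),
    class = "sweep_cohort")
  pops <- stats::setNames(rep(c("P", "Q"), each = 20), rownames(g))
  res <- apply_filter_cascade(co, stage = "scan", pops = pops)
  expect_equal(res$report$removed[res$report$step == "hwe"], 1L)
  expect_equal(res$cohort$sites$pos, 200L)
})
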