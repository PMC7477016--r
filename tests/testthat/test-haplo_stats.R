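test_that("EHH anchors: core = 1, distinct extensions = 0, identical haplotypes = 1", {
  toy <- make_toy_fixtures()$ehh
  # carriers of allele 0 at site 1 are {00, 01}: distinct at site 2 -> EHH 0
  p <- ehh(toy$haps, toy$positions, core = 1, allele = "derived", derived = 0L)
  expect_equal(p$right$ehh, c(1, 0))
  expect_equal(p$left$ehh, 1)      # nothing left of the core
  # identical haplotypes keep EHH at 1 everywhere
  twin <- matrix(rep(c(0L, 1L, 0L, 1L), 2), 2, 4, byrow = TRUE)
  p2 <- ehh(twin, c(10, 20, 30, 40), core = 2, allele = "derived")
  expect_equal(p2$right$ehh, c(1, 1, 1))
  expect_equal(p2$left$ehh, c(1, 1))
  # fewer than 2 carriers -> undefined profile
  p3 <- ehh(toy$haps, toy$positions, core = 1, allele = "all")
  expect_true(p3$defined)          # 4 haplotypes, pairs exist
  single <- matrix(c(1L, 0L, 0L, 0L), 4, 1)
  expect_false(ehh(single, 100, 1, allele = "derived")$defined)
})

test_that("EHH profiles match the string-counting oracle and are monotone", {
  for (seed in 1:12) {
    inst <- rand_hap_instance(seed)
    core <- sample(ncol(inst$haps), 1)
    for (mode in 0:2) {
      o <- oracle_ehh(inst$haps, inst$pos, core, mode)
      allele <- if (mode == 2) "all" else "derived"
      p <- ehh(inst$haps, inst$pos, core, allele = allele,
               derived = if (mode == 2) 1L else mode, max_gap = Inf)
      if (!isTRUE(p$defined)) {
        expect_equal(o$d0, 0)
        next
      }
      expect_equal(p$left$ehh, o$left$ehh, tolerance = 1e-9)
      expect_equal(p$right$ehh, o$right$ehh, tolerance = 1e-9)
      expect_true(all(diff(p$left$ehh) <= 1e-12))
      expect_true(all(diff(p$right$ehh) <= 1e-12))
      expect_true(all(p$left$ehh >= 0 & p$left$ehh <= 1))
    }
  }
})

test_that("iHH integrates trapezoids with cutoff interpolation", {
  mk <- function(lpos, lehh, rpos, rehh)
    structure(list(defined = TRUE, left = data.frame(pos = lpos, ehh = lehh),
                   right = data.frame(pos = rpos, ehh = rehh)),
              class = "ehh_profile")
  # one side [1.0, 0.5] over 1 kb at cutoff 0 -> 750
  expect_equal(ihh(mk(0, 1, c(0, 1000), c(1, 0.5)), cutoff = 0), 750)
  # flat profile of 1.0 over 10 kb on both sides -> 20000
  expect_equal(ihh(mk(c(0, -10000), c(1, 1), c(0, 10000), c(1, 1)),
                   cutoff = 0.05), 20000)
  # random profiles against numeric integration, both via the R path and
  # the scan engine
  for (seed in 13:20) {
    inst <- rand_hap_instance(seed)
    core <- sample(ncol(inst$haps), 1)
    p <- ehh(inst$haps, inst$pos, core, allele = "all", max_gap = Inf)
    expect_equal(ihh(p), oracle_ihh(p), tolerance = 1e-9)
    got <- sweepscan:::ihh_scan_cpp(inst$haps, as.numeric(inst$pos),
                                    core - 1L, 0.05, Inf, 2L)
    expect_equal(got, oracle_ihh(p), tolerance = 1e-9)
  }
})

test_that("iHS standardisation is bin-wise exact and raw scores match the oracle", {
  co <- fx_neutral()$cohort
  ihs <- suppressMessages(ihs_scan(co$haplo, co$sites))
  for (b in unique(ihs$bin[!ihs$pooled_bin])) {
    sub <- ihs$ihs[ihs$bin == b & !ihs$pooled_bin]
    if (length(sub) < 2) next
    expect_equal(mean(sub), 0, tolerance = 1e-9)
    expect_equal(stats::sd(sub), 1, tolerance = 1e-9)
  }
  # recompute one site's raw score via the profile oracles
  k <- which.max(ihs$abs_ihs)
  core <- match(ihs$pos[k], co$sites$pos)
  pa <- ehh(co$haplo, co$sites$pos, core, "ancestral")
  pd <- ehh(co$haplo, co$sites$pos, core, "derived")
  expect_equal(ihs$raw[k], log(oracle_ihh(pa) / oracle_ihh(pd)),
               tolerance = 1e-9)
  # the neutral tail is near its Gaussian mass
  expect_lt(abs(mean(ihs$abs_ihs > 2) - 0.046), 0.02)
})

test_that("xpEHH is zero between identical populations and antisymmetric", {
  co <- fx_small()$cohort
  h1 <- pop_haplotypes(co, fx_small()$pops, "POP1")
  h2 <- pop_haplotypes(co, fx_small()$pops, "POP2")
  same <- suppressMessages(xpehh_scan(h1, h1, co$sites))
  expect_true(all(abs(same$raw) < 1e-12))
  a <- suppressMessages(xpehh_scan(h1, h2, co$sites))
  b <- suppressMessages(xpehh_scan(h2, h1, co$sites))
  expect_equal(a$raw, -b$raw, tolerance = 1e-12)
  # shared-boundary variant stays defined and finite
  s <- suppressMessages(xpehh_scan(h1, h2, co$sites, boundary = "shared"))
  expect_true(all(is.finite(s$xpehh)))
})

test_that("a planted sweep drives xpEHH above the candidate threshold near its site", {
  hits <- 0
  for (i in 1:3) {
    sim <- fx_sweep(i)
    co <- sim$cohort
    h1 <- pop_haplotypes(co, sim$pops, "POP1")
    h2 <- pop_haplotypes(co, sim$pops, "POP2")
    xp <- suppressMessages(xpehh_scan(h1, h2, co$sites))
    near <- abs(xp$pos - sim$truth$sweep_pos) < 5e4
    hits <- hits + (max(xp$xpehh[near]) > 2.5)
    # and the sign convention points at population 1
    expect_gt(max(xp$xpehh[near]), max(-xp$xpehh[near]))
  }
  expect_gte(hits, 2)
})

test_that("a planted sweep elevates |iHS| around its site relative to background", {
  ratios <- vapply(1:3, function(i) {
    sim <- fx_sweep(i)
    co <- sim$cohort
    h1 <- pop_haplotypes(co, sim$pops, "POP1")
    ihs <- suppressMessages(ihs_scan(h1, co$sites))
    near <- abs(ihs$pos - sim$truth$sweep_pos) < 5e4
    mean(ihs$abs_ihs[near] > 2) / max(mean(ihs$abs_ihs[!near] > 2), 1e-6)
  }, 0)
  expect_gt(mean(ratios > 1), 0.5)
})
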