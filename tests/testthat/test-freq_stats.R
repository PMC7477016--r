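test_that("inbreeding F hits its analytic anchors", {
  # fully homozygous individuals at p = 0.5 sites -> F = 1
  g <- rbind(rep(0L, 6), rep(2L, 6), rep(c(0L, 2L), 3))
  rownames(g) <- c("i1", "i2", "i3")
  f <- inbreeding_f(g)
  expect_equal(unname(f), rep(1, 3))
  # a random-mating panel is centred on 0 within Monte-Carlo error
  co <- fx_neutral()$cohort
  f <- inbreeding_f(co$geno)
  expect_lt(abs(mean(f)), 0.02)
})

test_that("Tajima's D matches its closed form and is 0 at pi = S/a1", {
  a1 <- sum(1 / 1:9)
  expect_equal(tajima_d(10, 16, 16 / a1), 0)
  for (pi in c(1.3, 5, 12)) {
    expect_equal(tajima_d(10, 16, pi), oracle_tajima(10, 16, pi),
                 tolerance = 1e-12)
    expect_equal(sign(tajima_d(10, 16, pi)), sign(pi - 16 / a1))
  }
  expect_true(is.na(tajima_d(10, 0, 0)))   # S = 0 undefined, not zero
  expect_error(tajima_d(3, 5, 1), "at least 4")
})

test_that("windowed Tajima's D counts pairwise differences by hand", {
  # one singleton among 10 haplotypes: pi = 9/45 = 0.2
  hm <- matrix(0L, 10, 1)
  hm[1, 1] <- 1L
  st <- data.frame(chrom = "1", pos = 1500L)
  w <- windowed_tajima_d(hm, st, window_bp = 3000)
  expect_equal(w$S, 1L)
  expect_equal(w$pi, 0.2)
  # all-duplicate window: no segregating sites, D undefined
  hm2 <- matrix(1L, 10, 2)
  w2 <- windowed_tajima_d(hm2, data.frame(chrom = "1", pos = c(10L, 20L)))
  expect_equal(w2$S, 0L)
  expect_equal(w2$pi, 0)
  expect_true(is.na(w2$D))
})

test_that("windowed statistics are invariant to splitting at window boundaries", {
  co <- fx_neutral()$cohort
  full <- windowed_tajima_d(co$haplo, co$sites)
  cut <- 150000L  # a 3 kb multiple
  left <- co$sites$pos <= cut
  st2 <- co$sites
  st2$chrom[!left] <- "2"
  st2$pos[!left] <- st2$pos[!left] - cut
  parts <- windowed_tajima_d(co$haplo, st2)
  expect_equal(parts$D[parts$chrom == "1"], full$D[seq_len(cut / 3000)])
  n2 <- sum(parts$chrom == "2")
  expect_equal(parts$D[parts$chrom == "2"],
               full$D[cut / 3000 + seq_len(n2)])
})

test_that("Weir-Cockerham F_ST matches the ANOVA oracle and its limits", {
  # fixed difference with equal sample sizes
  f <- wc_fst(50, 50, 50, 0)
  expect_equal(f$fst, 1.0)
  # random configurations against the independently built oracle
  set.seed(11)
  for (k in 1:50) {
    n1 <- sample(4:80, 1); n2 <- sample(4:80, 1)
    ac1 <- sample(1:(n1 - 1), 1); ac2 <- sample(0:n2, 1)
    got <- wc_fst(n1, ac1, n2, ac2)$fst
    expect_equal(got, oracle_wc_fst(n1, ac1, n2, ac2), tolerance = 1e-12)
  }
  # monomorphic in both populations -> undefined
  expect_true(is.na(wc_fst(10, 0, 12, 0)$fst))
  expect_true(is.na(wc_fst(1, 1, 12, 6)$fst))
  # panmixia: two halves of one panel, mean per-site fst near 0
  co <- fx_neutral()$cohort
  half <- seq_len(nrow(co$geno)) <= nrow(co$geno) / 2
  pc <- pop_allele_counts(co$geno, stats::setNames(
    ifelse(half, "X", "Y"), rownames(co$geno)))
  f <- wc_fst(pc$X$n, pc$X$ac, pc$Y$n, pc$Y$ac)
  expect_lt(abs(mean(f$fst, na.rm = TRUE)), 0.01)
})

test_that("region-mean F_ST is a ratio of sums, invariant to site order", {
  fd <- data.frame(chrom = "1", pos = c(150L, 250L),
                   a = c(1, 0), b = c(1, 1), c = c(0, 0),
                   fst = c(0.5, 0))
  iv <- data.frame(chrom = "1", start = 0L, end = 1000L)
  expect_equal(region_mean_fst(fd, iv)$fst, 1 / 3)
  expect_equal(region_mean_fst(fd[2:1, ], iv)$fst, 1 / 3)
  one <- region_mean_fst(fd[1, ], iv)
  expect_equal(one$fst, fd$fst[1])
  expect_equal(region_mean_fst(fd, iv, method = "mean_of_ratios")$fst, 0.25)
  empty <- region_mean_fst(fd, data.frame(chrom = "2", start = 0L, end = 10L))
  expect_true(is.na(empty$fst))
})
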