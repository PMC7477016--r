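#' Per-individual inbreeding coefficient F
#'
#' Method-of-moments F from observed versus expected homozygosity:
#' `F = (O_hom - E_hom) / (L - E_hom)` per individual, where the expectation
#' sums, over that individual's called polymorphic sites,
#' `1 - 2 p (1 - p) * 2n/(2n - 1)` with `p` the sample alt-allele frequency
#' and `2n` the number of called alleles at the site.
#'
#' @param gm Dosage matrix (samples x sites).
#' @return Named numeric vector of F per individual; NA when an individual
#'   has no called polymorphic sites.
#' @export
inbreeding_f <- function(gm) {
  ss <- site_stats(gm)
  poly <- !is.na(ss$maf) & ss$maf > 0 & ss$n_called > 0
  if (!any(poly)) return(stats::setNames(rep(NA_real_, nrow(gm)), rownames(gm)))
  g <- gm[, poly, drop = FALSE]
  p <- ss$p[poly]
  twon <- 2 * ss$n_called[poly]
  e_site <- 1 - 2 * p * (1 - p) * twon / (twon - 1)
  called <- !is.na(g)
  o_hom <- rowSums(g == 0L | g == 2L, na.rm = TRUE)
  e_hom <- as.numeric(called %*% e_site)
  l_called <- rowSums(called)
  f <- (o_hom - e_hom) / (l_called - e_hom)
  f[l_called == 0] <- NA_real_
  stats::setNames(f, rownames(gm))
}

#' Tajima's D from summary quantities
#'
#' Standard constants: `a1 = sum 1/i`, `a2 = sum 1/i^2` (i = 1..n-1),
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`;
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))`.
#'
#' @param n Number of haplotypes (>= 4).
#' @param S Segregating sites (vectorised).
#' @param pi Mean pairwise differences (vectorised).
#' @return D; NA where S = 0 (undefined, not zero).
#' @export
tajima_d <- function(n, S, pi) {
  if (n < 4) stop("tajima_d needs at least 4 haplotypes")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  d <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  d[S == 0] <- NA_real_
  d
}

#' Windowed Tajima's D over a phased haplotype matrix
#'
#' Tiles each chromosome with fixed-span windows (default 3 kb), counts
#' segregating sites and mean pairwise differences per window from the
#' haplotypes of one population, and evaluates [tajima_d()].  Windows are
#' 0-based half-open; empty windows and windows with S = 0 are emitted with
#' undefined D so window counts stay auditable.
#'
#' @param hm Haplotype matrix (2N x L, 0/1).
#' @param sites data.frame with chrom and pos (1-based) per column of `hm`.
#' @param window_bp Window span in bp (default 3000).
#' @return data.frame: chrom, start, end, n_snps, S, pi, D.
#' @export
windowed_tajima_d <- function(hm, sites, window_bp = 3000) {
  n <- nrow(hm)
  cnt <- colSums(hm)
  seg <- cnt > 0 & cnt < n
  pi_site <- 2 * cnt * (n - cnt) / (n * (n - 1))
  out <- list()
  for (ch in unique(sites$chrom)) {
    on_ch <- which(sites$chrom == ch)
    pos0 <- sites$pos[on_ch] - 1L  # 0-based
    n_win <- floor(max(pos0) / window_bp) + 1L
    wstart <- (seq_len(n_win) - 1L) * window_bp
    wi <- findInterval(pos0, wstart)
    n_snps <- tabulate(wi, nbins = n_win)
    S <- tabulate(wi[seg[on_ch]], nbins = n_win)
    piw <- numeric(n_win)
    agg <- rowsum(pi_site[on_ch], wi)
    piw[as.integer(rownames(agg))] <- agg[, 1]
    out[[ch]] <- data.frame(chrom = ch, start = wstart,
                            end = wstart + window_bp, n_snps = n_snps,
                            S = S, pi = piw,
                            D = tajima_d(n, S, piw))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Weir-Cockerham F_ST variance components per site
#'
#' Two-population variance-components estimator on allele counts (phased
#' haplotypes count as independent allele draws): between-population
#' component `a` and within-population component `b` from the one-way
#' ANOVA of the binary allele indicator, with `c = 0` in the allele-based
#' layout, so that `fst = a/(a+b+c)`.
#'
#' @param n1,n2 Called allele (haplotype) counts per site in each population.
#' @param ac1,ac2 Alt-allele counts per site.
#' @return data.frame with components a, b, c and per-site `fst`; NA where a
#'   population has fewer than 2 called alleles or the site is monomorphic
#'   in both populations.
#' @export
wc_fst <- function(n1, ac1, n2, ac2) {
  r <- 2
  p1 <- ac1 / n1
  p2 <- ac2 / n2
  N <- n1 + n2
  pbar <- (ac1 + ac2) / N
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - r)
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  a <- (msp - msg) / nc
  b <- msg
  fst <- a / (a + b)
  undef <- n1 < 2 | n2 < 2 | (pbar %in% c(0, 1))
  a[undef] <- NA_real_; b[undef] <- NA_real_; fst[undef] <- NA_real_
  fst[!undef & (a + b) == 0] <- NA_real_
  data.frame(a = a, b = b, c = 0, fst = fst)
}

#' Region-mean F_ST by ratio of sums
#'
#' Aggregates per-site variance components over each interval as
#' `sum(a) / sum(a+b+c)` (ratio of sums, the low-bias convention); the
#' mean-of-ratios alternative is available via `method`.
#'
#' @param fst_df Output of [wc_fst()] with added chrom and pos columns.
#' @param intervals data.frame chrom/start/end (0-based half-open).
#' @param method `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @return `intervals` with an `fst` column (NA for empty intervals) and
#'   `n_snps` used.
#' @export
region_mean_fst <- function(fst_df, intervals,
                            method = c("ratio_of_sums", "mean_of_ratios")) {
  method <- match.arg(method)
  fst <- nsnp <- numeric(nrow(intervals))
  for (k in seq_len(nrow(intervals))) {
    inr <- fst_df$chrom == intervals$chrom[k] &
      (fst_df$pos - 1L) >= intervals$start[k] &
      (fst_df$pos - 1L) < intervals$end[k] & !is.na(fst_df$a)
    nsnp[k] <- sum(inr)
    if (!any(inr)) { fst[k] <- NA_real_; next }
    fst[k] <- if (method == "ratio_of_sums") {
      sum(fst_df$a[inr]) / sum(fst_df$a[inr] + fst_df$b[inr] + fst_df$c[inr])
    } else {
      mean(fst_df$fst[inr], na.rm = TRUE)
    }
  }
  cbind(intervals, data.frame(fst = fst, n_snps = as.integer(nsnp)))
}

#' Per-population allele counts from a dosage matrix
#'
#' @param gm Dosage matrix (samples x sites).
#' @param pops Named vector sample -> population.
#' @return List per population: `n` called allele count and `ac` alt count
#'   per site.
#' @export
pop_allele_counts <- function(gm, pops) {
  labs <- pops[rownames(gm)]
  if (any(is.na(labs))) stop("samples missing from population map")
  out <- list()
  for (pp in unique(labs)) {
    g <- gm[labs == pp, , drop = FALSE]
    called <- colSums(!is.na(g))
    out[[pp]] <- list(n = 2L * called, ac = colSums(g, na.rm = TRUE))
  }
  out
}

#' Haplotype rows belonging to one population
#'
#' @param cohort A phased `sweep_cohort`.
#' @param pops Named vector sample -> population.
#' @param pop Population label.
#' @return Haplotype matrix restricted to that population's samples.
#' @export
pop_haplotypes <- function(cohort, pops, pop) {
  if (is.null(cohort$haplo)) stop("cohort is not phased")
  soh <- attr(cohort$haplo, "sample_of_haplotype")
  h <- cohort$haplo[pops[soh] == pop, , drop = FALSE]
  attr(h, "sample_of_haplotype") <- soh[pops[soh] == pop]
  h
}
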