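#' Per-SNP f3 contribution
#'
#' For target C and sources A, B with allele frequencies a, b, c:
#' `(c - a)(c - b)` minus the finite-sample heterozygosity correction for
#' the target, `h_C / n_C` with `h_C = c (1 - c) n_C / (n_C - 1)`.
#' Significantly negative sums indicate that C is admixed between
#' populations related to A and B.
#'
#' @param a,b,c Allele frequencies in source A, source B and target C
#'   (vectorised).
#' @param n_c Called allele (chromosome) count in the target (>= 2).
#' @param correction Apply the target heterozygosity correction (default
#'   TRUE).
#' @return Per-SNP contribution(s).
#' @export
f3_per_snp <- function(a, b, c, n_c, correction = TRUE) {
  if (any(n_c < 2)) stop("n_c must be >= 2")
  if (any(c(a, b, c) < 0 | c(a, b, c) > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  out <- (c - a) * (c - b)
  if (correction) out <- out - c * (1 - c) / (n_c - 1)
  out
}

#' Three-population f3 admixture test with block jackknife
#'
#' `f3(C; A, B)` as the mean per-SNP contribution, with a standard error
#' from a weighted delete-one-block jackknife over contiguous physical
#' blocks (weights = block SNP counts) and `Z = f3 / SE`.  Negative Z is
#' evidence that the target derives ancestry from both sources.
#'
#' @param freq_a,freq_b,freq_c Allele frequencies per site.
#' @param n_c Called allele count in the target per site.
#' @param chrom,pos Site coordinates (blocks never span chromosomes).
#' @param block_span Block span in bp (default 5 Mb).
#' @param correction See [f3_per_snp()].
#' @param labels Optional c(target, sourceA, sourceB) labels.
#' @return An `f3_result`: list with f3, se, z, n_snps, n_blocks,
#'   block_span and labels.
#' @export
f3_test <- function(freq_a, freq_b, freq_c, n_c, chrom, pos,
                    block_span = 5e6, correction = TRUE, labels = NULL) {
  ok <- !(is.na(freq_a) | is.na(freq_b) | is.na(freq_c))
  # sites monomorphic across the union carry no information
  mono <- (freq_a == 0 & freq_b == 0 & freq_c == 0) |
    (freq_a == 1 & freq_b == 1 & freq_c == 1)
  ok <- ok & !mono
  contrib <- f3_per_snp(freq_a[ok], freq_b[ok], freq_c[ok],
                        if (length(n_c) > 1) n_c[ok] else n_c, correction)
  block <- paste(chrom[ok], floor((pos[ok] - 1) / block_span))
  block <- factor(block, levels = unique(block))
  g <- nlevels(block)
  if (g < 2) stop("need at least 2 non-empty blocks for the jackknife")
  n <- length(contrib)
  est <- mean(contrib)
  bsum <- tapply(contrib, block, sum)
  bn <- tapply(contrib, block, length)
  theta_j <- (sum(contrib) - bsum) / (n - bn)  # delete-one-block means
  # weighted jackknife (Busing et al.): h_j = n / m_j
  h <- n / bn
  theta_dot <- g * est - sum((1 - bn / n) * theta_j)
  tau <- h * est - (h - 1) * theta_j
  var_j <- mean((tau - theta_dot)^2 / (h - 1))
  se <- sqrt(var_j)
  structure(list(f3 = est, se = se, z = est / se, n_snps = n,
                 n_blocks = g, block_span = block_span,
                 labels = labels),
            class = "f3_result")
}

#' f3 test straight from a cohort and population map
#'
#' Computes per-population allele frequencies (listwise-dropping sites
#' undefined in any of the three populations) and runs [f3_test()].
#'
#' @param cohort A `sweep_cohort`.
#' @param pops Named vector sample -> population.
#' @param target,source_a,source_b Population labels.
#' @param ... Passed to [f3_test()].
#' @return An `f3_result`.
#' @export
f3_from_cohort <- function(cohort, pops, target, source_a, source_b, ...) {
  cnts <- pop_allele_counts(cohort$geno, pops)
  for (pp in c(target, source_a, source_b))
    if (!pp %in% names(cnts)) stop("population not in map: ", pp)
  fr <- function(pp) ifelse(cnts[[pp]]$n > 0, cnts[[pp]]$ac / cnts[[pp]]$n, NA_real_)
  f3_test(fr(source_a), fr(source_b), fr(target), cnts[[target]]$n,
          cohort$sites$chrom, cohort$sites$pos,
          labels = c(target, source_a, source_b), ...)
}

#' @export
print.f3_result <- function(x, ...) {
  lab <- if (is.null(x$labels)) "" else
    sprintf("f3(%s; %s, %s): ", x$labels[1], x$labels[2], x$labels[3])
  cat(sprintf("%sf3 = %.6g, SE = %.3g, Z = %.2f (%d SNPs, %d blocks)\n",
              lab, x$f3, x$se, x$z, x$n_snps, x$n_blocks))
  invisible(x)
}
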