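#' Filtering configuration
#'
#' Thresholds for the QC cascade.  The defaults are the study conditions:
#' sites with missing data above 10% are removed, then sites with minor
#' allele count below 3, minor allele frequency below 0.01, and
#' Hardy-Weinberg exact p below 0.001; individuals with more than 10%
#' missing data are dropped afterwards.  The population stage then thins to
#' pairwise r-squared below 0.1; the scan stage instead removes sites with
#' MAF below 0.05.
#'
#' @param max_site_missing Maximum per-site missing fraction (default 0.10).
#' @param min_minor_allele_count Minimum minor allele count (default 3).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @param hwe_p_min Minimum Hardy-Weinberg exact p (default 0.001).
#' @param max_indiv_missing Maximum per-individual missing fraction (0.10).
#' @param ld_r2_max r-squared ceiling for LD thinning (default 0.1).
#' @param scan_maf_min MAF floor for the selection-scan stage (default 0.05).
#' @param ld_window_snps,ld_step_snps Sliding-window size/step (in SNPs) for
#'   LD thinning.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_site_missing = 0.10, min_minor_allele_count = 3L,
                          min_maf = 0.01, hwe_p_min = 0.001,
                          max_indiv_missing = 0.10, ld_r2_max = 0.1,
                          scan_maf_min = 0.05, ld_window_snps = 50L,
                          ld_step_snps = 5L) {
  fr <- c(max_site_missing, min_maf, hwe_p_min, max_indiv_missing,
          ld_r2_max, scan_maf_min)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  structure(list(max_site_missing = max_site_missing,
                 min_minor_allele_count = as.integer(min_minor_allele_count),
                 min_maf = min_maf, hwe_p_min = hwe_p_min,
                 max_indiv_missing = max_indiv_missing,
                 ld_r2_max = ld_r2_max, scan_maf_min = scan_maf_min,
                 ld_window_snps = as.integer(ld_window_snps),
                 ld_step_snps = as.integer(ld_step_snps)),
            class = "filter_config")
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test from genotype counts: all heterozygote counts
#' compatible with the observed allele counts are enumerated and the
#' probabilities of configurations no more likely than the observed one are
#' summed (no mid-p correction).
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("counts must be non-negative")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype required")
  na <- 2L * n_hom_alt + n_het            # alt allele count
  nr <- min(na, 2L * n - na)              # rarer allele count
  hets <- seq.int(nr %% 2L, nr, by = 2L)  # feasible heterozygote counts
  # log P(n_het = h | n, nr) up to a shared constant
  homr <- (nr - hets) / 2L
  homc <- n - hets - homr
  lp <- hets * log(2) - lfactorial(homr) - lfactorial(hets) - lfactorial(homc)
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Per-site summary statistics
#'
#' @param gm Dosage matrix (samples x sites, values 0/1/2, NA missing).
#' @return data.frame with n_called, call_rate, alt frequency `p`, `maf`,
#'   `mac`, genotype counts and pooled Hardy-Weinberg exact p per site.
#'   Sites with zero called genotypes carry NA statistics.
#' @export
site_stats <- function(gm) {
  n_samp <- nrow(gm)
  n0 <- colSums(gm == 0L, na.rm = TRUE)
  n1 <- colSums(gm == 1L, na.rm = TRUE)
  n2 <- colSums(gm == 2L, na.rm = TRUE)
  n_called <- n0 + n1 + n2
  ac <- 2L * n2 + n1
  p <- ifelse(n_called > 0, ac / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  mac <- pmin(ac, 2L * n_called - ac)
  hwe_p <- rep(NA_real_, ncol(gm))
  ok <- n_called > 0
  hwe_p[ok] <- mapply(hwe_exact_test, n0[ok], n1[ok], n2[ok])
  data.frame(n_called = n_called, call_rate = n_called / n_samp,
             p = p, maf = maf, mac = ifelse(ok, mac, NA_integer_),
             n_hom_ref = n0, n_het = n1, n_hom_alt = n2, hwe_p = hwe_p)
}

#' LD thinning by pairwise r-squared
#'
#' Slides a window of `window_snps` consecutive retained sites along each
#' chromosome (step `step_snps`) and, whenever the squared Pearson
#' correlation of dosages of a retained pair reaches `r2_max`, drops the
#' later-position member.  Missing dosages are mean-imputed within the
#' correlation computation only.  Passes repeat until no site is removed, so
#' the kept set satisfies the r-squared ceiling over windows of the kept
#' sequence and the operation is idempotent.
#'
#' @param gm Dosage matrix (samples x sites).
#' @param r2_max r-squared ceiling (pairs at or above it conflict).
#' @param window_snps,step_snps Window size and step in SNPs.
#' @param chrom Optional chromosome label per site; windows never span
#'   chromosomes.
#' @return Integer vector of retained site indices (increasing).
#' @export
ld_prune <- function(gm, r2_max = 0.1, window_snps = 50L, step_snps = 5L,
                     chrom = NULL) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  S <- ncol(gm)
  if (is.null(chrom)) chrom <- rep("1", S)
  kept <- rep(TRUE, S)
  imp <- apply(gm, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  imp <- matrix(imp, nrow = nrow(gm))
  repeat {
    removed_any <- FALSE
    for (ch in unique(chrom)) {
      repeat {
        idx <- which(kept & chrom == ch)
        n <- length(idx)
        if (n < 2) break
        removed_pass <- FALSE
        starts <- unique(c(seq(1L, max(1L, n - 1L), by = step_snps)))
        for (w0 in starts) {
          win <- idx[w0:min(w0 + window_snps - 1L, n)]
          win <- win[kept[win]]
          if (length(win) < 2) next
          cc <- suppressWarnings(stats::cor(imp[, win, drop = FALSE]))
          cc[is.na(cc)] <- 0
          m <- length(win)
          for (i in seq_len(m - 1L)) {
            if (!kept[win[i]]) next
            for (j in seq((i + 1L), m)) {
              if (!kept[win[j]]) next
              if (cc[i, j]^2 >= r2_max) {
                kept[win[j]] <- FALSE  # later position dropped
                removed_pass <- TRUE
              }
            }
          }
        }
        if (removed_pass) removed_any <- TRUE else break
      }
    }
    if (!removed_any) break
  }
  which(kept)
}

#' Apply the QC filtering cascade
#'
#' Steps, in order: site missingness, minor allele count, minor allele
#' frequency, Hardy-Weinberg exact test (per population when a population
#' map is given, removing sites failing in any population; pooled
#' otherwise), individual missingness, and a stage-specific step (LD
#' thinning for the `population` stage, a MAF >= `scan_maf_min` floor for
#' the `scan` stage, recomputed on the surviving individuals).
#'
#' @param cohort A `sweep_cohort`.
#' @param cfg A [filter_config()].
#' @param stage `"population"` or `"scan"`.
#' @param pops Optional named vector (sample -> population) for per-population
#'   Hardy-Weinberg testing.
#' @param hwe_scope `"per_pop"` (default when `pops` given) or `"pooled"`.
#' @return List with the filtered `cohort`, a `report` data.frame (step,
#'   removed, remaining), and `removed_individuals`.
#' @export
apply_filter_cascade <- function(cohort, cfg = filter_config(),
                                 stage = c("population", "scan"),
                                 pops = NULL,
                                 hwe_scope = if (is.null(pops)) "pooled" else "per_pop") {
  stage <- match.arg(stage)
  gm <- cohort$geno
  keep_site <- rep(TRUE, ncol(gm))
  report <- data.frame(step = character(0), removed = integer(0),
                       remaining = integer(0))
  note <- function(step, removed) {
    report <<- rbind(report, data.frame(
      step = step, removed = removed, remaining = sum(keep_site)))
  }

  ss <- site_stats(gm)
  # 1. site missingness
  bad <- keep_site & (1 - ss$call_rate) > cfg$max_site_missing
  keep_site[bad] <- FALSE; note("site_missingness", sum(bad))
  # 2. minor allele count (monomorphic and zero-call sites fall here too)
  bad <- keep_site & (is.na(ss$mac) | ss$mac < cfg$min_minor_allele_count)
  keep_site[bad] <- FALSE; note("minor_allele_count", sum(bad))
  # 3. minor allele frequency
  bad <- keep_site & ss$maf < cfg$min_maf
  bad[is.na(bad)] <- FALSE
  keep_site[bad] <- FALSE; note("maf", sum(bad))
  # 4. Hardy-Weinberg
  if (hwe_scope == "per_pop" && !is.null(pops)) {
    fail <- rep(FALSE, ncol(gm))
    for (pp in unique(pops[cohort$samples])) {
      rows <- cohort$samples[pops[cohort$samples] == pp]
      sp <- site_stats(gm[rows, , drop = FALSE])
      fail <- fail | (!is.na(sp$hwe_p) & sp$hwe_p < cfg$hwe_p_min)
    }
  } else {
    fail <- !is.na(ss$hwe_p) & ss$hwe_p < cfg$hwe_p_min
  }
  bad <- keep_site & fail
  keep_site[bad] <- FALSE; note("hwe", sum(bad))

  # 5. individual missingness, on surviving sites
  gm2 <- gm[, keep_site, drop = FALSE]
  miss_ind <- rowMeans(is.na(gm2))
  drop_ind <- miss_ind > cfg$max_indiv_missing
  removed_individuals <- rownames(gm2)[drop_ind]
  gm2 <- gm2[!drop_ind, , drop = FALSE]
  report <- rbind(report, data.frame(step = "individual_missingness",
                                     removed = sum(drop_ind),
                                     remaining = sum(keep_site)))

  # 6. stage-specific
  site_idx <- which(keep_site)
  if (stage == "population") {
    kept_rel <- ld_prune(gm2, r2_max = cfg$ld_r2_max,
                         window_snps = cfg$ld_window_snps,
                         step_snps = cfg$ld_step_snps,
                         chrom = cohort$sites$chrom[site_idx])
    removed <- length(site_idx) - length(kept_rel)
    site_idx <- site_idx[kept_rel]
    step_name <- "ld_prune"
  } else {
    ss2 <- site_stats(gm2)
    keep_rel <- !is.na(ss2$maf) & ss2$maf >= cfg$scan_maf_min
    removed <- sum(!keep_rel)
    site_idx <- site_idx[keep_rel]
    step_name <- "scan_maf"
  }
  report <- rbind(report, data.frame(step = step_name, removed = removed,
                                     remaining = length(site_idx)))
  if (length(site_idx) == 0) warning("all sites removed by the filter cascade")

  out <- cohort
  out$sites <- cohort$sites[site_idx, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$samples <- setdiff(cohort$samples, removed_individuals)
  out$geno <- cohort$geno[out$samples, site_idx, drop = FALSE]
  if (!is.null(cohort$haplo)) {
    hap_keep <- attr(cohort$haplo, "sample_of_haplotype") %in% out$samples
    out$haplo <- cohort$haplo[hap_keep, site_idx, drop = FALSE]
    attr(out$haplo, "sample_of_haplotype") <-
      attr(cohort$haplo, "sample_of_haplotype")[hap_keep]
  }
  attr(report, "mac_rule") <- "minor-allele count < min_minor_allele_count"
  list(cohort = out, report = report, removed_individuals = removed_individuals)
}
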