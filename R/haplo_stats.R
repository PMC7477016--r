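#' EHH decay profile around a core site
#'
#' Extended haplotype homozygosity: the probability that two randomly chosen
#' haplotypes of the core set are identical over the span from the core to a
#' given site, normalised to 1 at the core.  For `allele = "all"` the core
#' set is every haplotype and the denominator is the pair-homozygosity at
#' the core site itself (the allele-agnostic profile used for
#' cross-population comparison).
#'
#' @param hm Haplotype matrix (haplotypes x sites, 0/1).
#' @param positions bp position per site.
#' @param core Site index (1-based column of `hm`).
#' @param allele `"derived"`, `"ancestral"` or `"all"`.
#' @param derived Coded value (0 or 1) of the derived allele at the core
#'   (default 1, i.e. the alt/derived coding used by the simulator).
#' @param max_gap Profile truncated at inter-SNP gaps above this (bp).
#' @return An `ehh_profile`: list with `left` and `right` data.frames
#'   (pos, ehh; starting at the core), `n_core`, `allele`, `core`,
#'   and `defined`.
#' @export
ehh <- function(hm, positions, core, allele = c("derived", "ancestral", "all"),
                derived = 1L, max_gap = 200000) {
  allele <- match.arg(allele)
  mode <- switch(allele, all = 2L, derived = as.integer(derived),
                 ancestral = 1L - as.integer(derived))
  prof <- ehh_profile_cpp(hm, as.numeric(positions), as.integer(core) - 1L,
                          mode, max_gap)
  if (!isTRUE(prof$defined))
    return(structure(list(defined = FALSE, core = core, allele = allele,
                          n_core = prof$n_core), class = "ehh_profile"))
  structure(list(defined = TRUE, core = core, allele = allele,
                 n_core = prof$n_core, d0 = prof$d0,
                 left = prof$left, right = prof$right),
            class = "ehh_profile")
}

#' Integrated EHH (iHH) of a profile
#'
#' Trapezoidal integral of EHH against physical position, both directions
#' summed, each truncated at the first site where EHH drops below `cutoff`
#' (the crossing point is interpolated linearly); if the profile never
#' crosses, integration runs to its truncation point (chromosome end or
#' gap).
#'
#' @param profile An [ehh()] profile.
#' @param cutoff EHH floor (default 0.05).
#' @return iHH in bp x homozygosity units; NA for undefined profiles.
#' @export
ihh <- function(profile, cutoff = 0.05) {
  if (!isTRUE(profile$defined)) return(NA_real_)
  one_side <- function(df) {
    d <- abs(df$pos - df$pos[1])
    e <- df$ehh
    tot <- 0
    if (length(d) < 2) return(0)
    for (j in 2:length(d)) {
      if (e[j] < cutoff) {
        xstar <- d[j - 1] + (e[j - 1] - cutoff) / (e[j - 1] - e[j]) * (d[j] - d[j - 1])
        return(tot + (e[j - 1] + cutoff) / 2 * (xstar - d[j - 1]))
      }
      tot <- tot + (e[j - 1] + e[j]) / 2 * (d[j] - d[j - 1])
    }
    tot
  }
  one_side(profile$left) + one_side(profile$right)
}

#' Intra-population iHS scan
#'
#' For every site above the MAF floor, integrates EHH separately over the
#' carriers of the ancestral and of the derived allele, takes
#' `raw = ln(iHH_A / iHH_D)`, and standardises within derived-allele
#' frequency bins so extreme scores are comparable across frequencies.
#' Sites whose ancestral state is unknown fall back to ref-as-ancestral and
#' are flagged (`aa_fallback`); only absolute scores are meaningful there.
#'
#' @param hm Phased haplotype matrix of one population (0 = ref, 1 = alt).
#' @param sites Site table (chrom, pos; optionally ancestral/ref/alt and
#'   aa_fallback from [read_vcf()]).
#' @param maf_min MAF floor (default 0.05).
#' @param freq_bin_width Derived-frequency bin width for standardisation.
#' @param cutoff,max_gap Integration controls, see [ihh()].
#' @return data.frame per retained site: chrom, pos, p_derived, ihh_a,
#'   ihh_d, raw, ihs, abs_ihs, bin, pooled_bin, aa_fallback.  The number of
#'   sites excluded for undefined iHH is in `attr(, "n_excluded")`.
#' @export
ihs_scan <- function(hm, sites, maf_min = 0.05, freq_bin_width = 0.05,
                     cutoff = 0.05, max_gap = 200000) {
  n <- nrow(hm)
  p_alt <- colMeans(hm)
  maf <- pmin(p_alt, 1 - p_alt)
  derived_is_alt <- if ("ancestral" %in% names(sites)) {
    ifelse(is.na(sites$ancestral) | sites$ancestral == sites$ref, TRUE,
           FALSE)
  } else rep(TRUE, ncol(hm))
  fallback <- if ("aa_fallback" %in% names(sites)) sites$aa_fallback
              else rep(FALSE, ncol(hm))

  cores <- which(maf >= maf_min)
  pos <- as.numeric(sites$pos)
  ihh0 <- ihh_scan_cpp(hm, pos, cores - 1L, cutoff, max_gap, 0L)
  ihh1 <- ihh_scan_cpp(hm, pos, cores - 1L, cutoff, max_gap, 1L)
  da <- derived_is_alt[cores]
  ihh_d <- ifelse(da, ihh1, ihh0)
  ihh_a <- ifelse(da, ihh0, ihh1)
  p_derived <- ifelse(da, p_alt[cores], 1 - p_alt[cores])
  raw <- log(ihh_a / ihh_d)
  ok <- is.finite(raw)
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message("ihs_scan: excluded ", n_excluded, " site(s) with undefined iHH")

  out <- data.frame(chrom = sites$chrom[cores], pos = sites$pos[cores],
                    p_derived = p_derived, ihh_a = ihh_a, ihh_d = ihh_d,
                    raw = raw, aa_fallback = fallback[cores])[ok, , drop = FALSE]
  nb <- ceiling(1 / freq_bin_width)
  out$bin <- pmin(floor(out$p_derived / freq_bin_width), nb - 1L)
  mu <- tapply(out$raw, out$bin, mean)
  sdv <- tapply(out$raw, out$bin, stats::sd)
  cnt <- tapply(out$raw, out$bin, length)
  sparse <- is.na(sdv) | sdv == 0 | cnt < 2
  pooled_mu <- mean(out$raw)
  pooled_sd <- stats::sd(out$raw)
  bm <- mu[as.character(out$bin)]
  bs <- sdv[as.character(out$bin)]
  pooled <- sparse[as.character(out$bin)]
  bm[pooled] <- pooled_mu
  bs[pooled] <- pooled_sd
  out$ihs <- (out$raw - bm) / bs
  out$abs_ihs <- abs(out$ihs)
  out$pooled_bin <- unname(pooled)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Cross-population xpEHH scan
#'
#' Allele-agnostic EHH is integrated within each population at every shared
#' site and `raw = ln(iES_pop1 / iES_pop2)` is standardised genome-wide.
#' Positive extremes mean longer haplotypes (candidate selection) in
#' population 1.  By default each population's profile is integrated to its
#' own cutoff crossing; `boundary = "shared"` instead truncates both at the
#' crossing of the pooled-population profile.
#'
#' @param hm1,hm2 Phased haplotype matrices over the same site set.
#' @param sites Site table (chrom, pos).
#' @param maf_min Floor on the pooled MAF (default 0.05).
#' @param cutoff,max_gap Integration controls.
#' @param boundary `"independent"` (default) or `"shared"`.
#' @return data.frame: chrom, pos, ies1, ies2, raw, xpehh;
#'   `attr(, "n_excluded")` counts sites with undefined iES.
#' @export
xpehh_scan <- function(hm1, hm2, sites, maf_min = 0.05, cutoff = 0.05,
                       max_gap = 200000, boundary = c("independent", "shared")) {
  boundary <- match.arg(boundary)
  if (ncol(hm1) != ncol(hm2)) stop("populations must share the site set")
  p <- colMeans(rbind(hm1, hm2))
  maf <- pmin(p, 1 - p)
  cores <- which(maf >= maf_min)
  pos <- as.numeric(sites$pos)
  bounds <- NULL
  if (boundary == "shared") {
    pooled <- rbind(hm1, hm2)
    bounds <- ehh_crossing_cpp(pooled, pos, cores - 1L, cutoff, max_gap)
  }
  ies1 <- ihh_scan_cpp(hm1, pos, cores - 1L, cutoff, max_gap, 2L, bounds)
  ies2 <- ihh_scan_cpp(hm2, pos, cores - 1L, cutoff, max_gap, 2L, bounds)
  raw <- log(ies1 / ies2)
  ok <- is.finite(raw)
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message("xpehh_scan: excluded ", n_excluded, " site(s) with undefined iES")
  out <- data.frame(chrom = sites$chrom[cores], pos = sites$pos[cores],
                    ies1 = ies1, ies2 = ies2, raw = raw)[ok, , drop = FALSE]
  out$xpehh <- (out$raw - mean(out$raw)) / stats::sd(out$raw)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' @export
print.ehh_profile <- function(x, ...) {
  if (!isTRUE(x$defined)) {
    cat("ehh_profile: undefined (n_core =", x$n_core, ")\n")
  } else {
    cat("ehh_profile: core", x$core, "allele", x$allele, "n_core", x$n_core,
        "; left", nrow(x$left) - 1, "sites, right", nrow(x$right) - 1, "sites\n")
  }
  invisible(x)
}
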