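#' 100 kb iHS enrichment windows
#'
#' Divides each chromosome into fixed bins (default 100 kb), counts SNPs and
#' SNPs with |iHS| above `ihs_thresh` per bin, and flags as significant the
#' included bins (those with at least `min_snps` SNPs) whose extreme
#' fraction reaches the top `top_q` quantile of included-bin fractions.
#' Ties at the quantile boundary are all retained.
#'
#' @param ihs data.frame from [ihs_scan()] (needs chrom, pos, abs_ihs).
#' @param bin_bp Bin span (default 100000).
#' @param ihs_thresh |iHS| threshold for "extreme" (default 2.0, strict).
#' @param min_snps Minimum SNPs for a bin to be included (default 20).
#' @param top_q Upper tail mass called significant (default 0.01).
#' @return data.frame: chrom, start, end, n_snps, n_extreme, fraction,
#'   included, significant; the fraction cutoff is in `attr(, "cutoff")`.
#' @export
bin_ihs <- function(ihs, bin_bp = 100000, ihs_thresh = 2.0, min_snps = 20L,
                    top_q = 0.01) {
  out <- list()
  for (ch in unique(ihs$chrom)) {
    d <- ihs[ihs$chrom == ch, ]
    pos0 <- d$pos - 1L
    n_win <- floor(max(pos0) / bin_bp) + 1L
    wi <- floor(pos0 / bin_bp) + 1L
    n_snps <- tabulate(wi, nbins = n_win)
    n_extreme <- tabulate(wi[d$abs_ihs > ihs_thresh], nbins = n_win)
    out[[ch]] <- data.frame(chrom = ch,
                            start = (seq_len(n_win) - 1L) * bin_bp,
                            end = seq_len(n_win) * bin_bp,
                            n_snps = n_snps, n_extreme = n_extreme)
  }
  w <- do.call(rbind, out)
  rownames(w) <- NULL
  w$fraction <- ifelse(w$n_snps > 0, w$n_extreme / w$n_snps, NA_real_)
  w$included <- w$n_snps >= min_snps
  w$significant <- FALSE
  if (!any(w$included)) {
    warning("no bins reach the SNP floor; empty significant set")
    attr(w, "cutoff") <- NA_real_
    return(w)
  }
  cutoff <- stats::quantile(w$fraction[w$included], 1 - top_q, names = FALSE)
  # a bin with no extreme SNP is never significant, even when every
  # fraction is zero and the quantile collapses to zero
  w$significant <- w$included & w$fraction >= cutoff & w$fraction > 0
  attr(w, "cutoff") <- cutoff
  w
}

#' Annotate windows or peak sites with overlapping genes
#'
#' Windows (chrom/start/end, 0-based half-open) are annotated with every
#' gene whose interval overlaps them; peak sites (chrom/pos, 1-based) with
#' every gene within `flank_bp` of the site.
#'
#' @param x data.frame of windows (chrom, start, end) or peaks (chrom, pos).
#' @param genes Gene intervals as from [read_intervals()].
#' @param flank_bp Flank for peak annotation (default 100000; ignored for
#'   windows).
#' @return Long data.frame: one row per (window/peak, gene) assignment.
#' @export
annotate_genes <- function(x, genes, flank_bp = 100000) {
  res <- list()
  peaks <- "pos" %in% names(x) && !"start" %in% names(x)
  for (k in seq_len(nrow(x))) {
    g <- genes[genes$chrom == x$chrom[k], , drop = FALSE]
    if (peaks) {
      p0 <- x$pos[k] - 1L  # site as 0-based point
      dist <- pmax(0, pmax(g$start - p0, p0 - (g$end - 1L)))
      hit <- dist <= flank_bp
    } else {
      hit <- g$start < x$end[k] & g$end > x$start[k]
    }
    if (!any(hit)) next
    res[[length(res) + 1]] <- cbind(
      x[rep(k, sum(hit)), , drop = FALSE],
      data.frame(gene = g$name[hit], gene_start = g$start[hit],
                 gene_end = g$end[hit], row.names = NULL))
  }
  if (!length(res))
    return(cbind(x[0, , drop = FALSE],
                 data.frame(gene = character(0), gene_start = integer(0),
                            gene_end = integer(0))))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Differential (selected-in-A-but-not-B) candidate windows and sites
#'
#' Step 1 keeps the windows of population A with more than `min_extreme`
#' SNPs of |iHS| above `ihs_thresh`; step 2 drops windows that also pass in
#' population B; step 3 (optional) keeps, within the surviving windows,
#' sites whose selected-allele frequency has reached `fix_thresh` in A but
#' not in B.
#'
#' @param ihs_a,ihs_b [ihs_scan()] tables for the two populations.
#' @param bin_bp Window span (default 100000).
#' @param ihs_thresh Extreme |iHS| threshold (default 2.0).
#' @param min_extreme Required extreme-SNP count per window, strict
#'   (default 20).
#' @param freq_a,freq_b Optional derived-allele frequencies aligned to
#'   `ihs_a`'s sites (named by `chrom:pos` or in the same order).
#' @param fix_thresh Optional fixation threshold for step 3.
#' @return List with `windows` (retained differential windows) and `sites`
#'   (extreme sites inside them, frequency-filtered when requested).
#' @export
candidate_sites <- function(ihs_a, ihs_b, bin_bp = 100000, ihs_thresh = 2.0,
                            min_extreme = 20L, freq_a = NULL, freq_b = NULL,
                            fix_thresh = NULL) {
  wa <- bin_ihs(ihs_a, bin_bp = bin_bp, ihs_thresh = ihs_thresh, min_snps = 0L)
  wb <- bin_ihs(ihs_b, bin_bp = bin_bp, ihs_thresh = ihs_thresh, min_snps = 0L)
  pass_a <- wa[wa$n_extreme > min_extreme, , drop = FALSE]
  key <- function(w) paste(w$chrom, w$start)
  pass_b_keys <- key(wb[wb$n_extreme > min_extreme, , drop = FALSE])
  wres <- pass_a[!key(pass_a) %in% pass_b_keys, , drop = FALSE]
  rownames(wres) <- NULL

  sites <- ihs_a[ihs_a$abs_ihs > ihs_thresh, , drop = FALSE]
  inwin <- rep(FALSE, nrow(sites))
  for (k in seq_len(nrow(wres)))
    inwin <- inwin | (sites$chrom == wres$chrom[k] &
                        (sites$pos - 1L) >= wres$start[k] &
                        (sites$pos - 1L) < wres$end[k])
  sites <- sites[inwin, , drop = FALSE]
  if (!is.null(fix_thresh) && !is.null(freq_a) && !is.null(freq_b) &&
      nrow(sites) > 0) {
    idkey <- paste(ihs_a$chrom, ihs_a$pos)
    fa <- freq_a[match(paste(sites$chrom, sites$pos), idkey)]
    fb <- freq_b[match(paste(sites$chrom, sites$pos), idkey)]
    sites <- sites[!is.na(fa) & !is.na(fb) &
                     fa >= fix_thresh & fb < fix_thresh, , drop = FALSE]
  }
  rownames(sites) <- NULL
  list(windows = wres[, c("chrom", "start", "end", "n_snps", "n_extreme",
                          "fraction")], sites = sites)
}

#' Per-gene evidence table
#'
#' Aggregates the scan statistics over each gene interval: max and mean
#' |iHS|, extreme-SNP counts and their fraction, mean Tajima's D over the
#' 3 kb bins overlapping the gene, ratio-of-sums F_ST over SNPs in the
#' gene, and max xpEHH.
#'
#' @param genes Gene intervals ([read_intervals()] layout).
#' @param ihs [ihs_scan()] table of the focal population.
#' @param xpehh [xpehh_scan()] table (focal vs comparison population).
#' @param tajima [windowed_tajima_d()] table of the focal population.
#' @param fst [wc_fst()] components with chrom/pos columns.
#' @param ihs_thresh Extreme threshold for the count columns (default 2.0).
#' @return data.frame, one row per gene, with the aggregate columns.
#' @export
gene_evidence <- function(genes, ihs, xpehh, tajima, fst, ihs_thresh = 2.0) {
  n <- nrow(genes)
  out <- data.frame(gene = genes$name, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    ihs_max = NA_real_, ihs_mean = NA_real_,
                    n_extreme = 0L, n_extreme_signed = 0L, n_total = 0L,
                    freq_extreme = NA_real_, tajima_mean = NA_real_,
                    fst_mean = NA_real_, xpehh_max = NA_real_)
  for (k in seq_len(n)) {
    ing <- function(df) df$chrom == genes$chrom[k] &
      (df$pos - 1L) >= genes$start[k] & (df$pos - 1L) < genes$end[k]
    si <- ihs[ing(ihs), ]
    if (nrow(si) > 0) {
      out$ihs_max[k] <- max(si$abs_ihs)
      out$ihs_mean[k] <- mean(si$abs_ihs)
      out$n_extreme[k] <- sum(si$abs_ihs > ihs_thresh)
      out$n_extreme_signed[k] <- sum(si$ihs > ihs_thresh)
      out$n_total[k] <- nrow(si)
      out$freq_extreme[k] <- out$n_extreme[k] / out$n_total[k]
    }
    tw <- tajima[tajima$chrom == genes$chrom[k] &
                   tajima$start < genes$end[k] &
                   tajima$end > genes$start[k] & !is.na(tajima$D), ]
    if (nrow(tw) > 0) out$tajima_mean[k] <- mean(tw$D)
    sf <- fst[ing(fst) & !is.na(fst$a), ]
    if (nrow(sf) > 0)
      out$fst_mean[k] <- sum(sf$a) / sum(sf$a + sf$b + sf$c)
    sx <- xpehh[ing(xpehh), ]
    if (nrow(sx) > 0) out$xpehh_max[k] <- max(sx$xpehh)
  }
  out
}

#' Gate and rank genes by combined evidence
#'
#' Candidate genes pass an F_ST gate (at or above the `fst_quantile`
#' quantile of gene-level F_ST means) and an xpEHH gate (max above
#' `xpehh_min`).  Candidates are then ranked best-first on each of Tajima's
#' D mean, F_ST mean and xpEHH max (larger = stronger = rank 1, average
#' ranks on ties) and the rank score is the sum of the three ranks; output
#' is sorted ascending by rank score.
#'
#' @param evidence [gene_evidence()] table.
#' @param fst_quantile F_ST gate quantile (default 0.95).
#' @param xpehh_min xpEHH gate (default 2.5, strict).
#' @return The gated rows with rank_tajima, rank_fst, rank_xpehh and
#'   rank_score columns, ordered by rank_score.
#' @export
rank_genes <- function(evidence, fst_quantile = 0.95, xpehh_min = 2.5) {
  gate_fst <- stats::quantile(evidence$fst_mean, fst_quantile, na.rm = TRUE,
                              names = FALSE)
  cand <- evidence[!is.na(evidence$fst_mean) & evidence$fst_mean >= gate_fst &
                     !is.na(evidence$xpehh_max) &
                     evidence$xpehh_max > xpehh_min, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  rk <- function(x) rank(-x, ties.method = "average", na.last = "keep")
  cand$rank_tajima <- rk(cand$tajima_mean)
  cand$rank_fst <- rk(cand$fst_mean)
  cand$rank_xpehh <- rk(cand$xpehh_max)
  cand$rank_score <- cand$rank_tajima + cand$rank_fst + cand$rank_xpehh
  cand <- cand[order(cand$rank_score), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Intersection of named interval collections
#'
#' Standard sweep-line intersection of half-open intervals: the output
#' covers exactly the positions present in every collection, with the
#' contributing set names carried along.
#'
#' @param sets Named list of data.frames (chrom, start, end).
#' @return data.frame chrom, start, end, sources.
#' @export
intersect_evidence <- function(sets) {
  if (length(sets) == 0) stop("no interval collections given")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sources = character(0))
  if (any(vapply(sets, nrow, 0L) == 0)) return(empty)
  pair_intersect <- function(a, b) {
    res <- list()
    for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
      aa <- a[a$chrom == ch, ]; bb <- b[b$chrom == ch, ]
      for (i in seq_len(nrow(aa))) {
        s <- pmax(aa$start[i], bb$start)
        e <- pmin(aa$end[i], bb$end)
        keep <- s < e
        if (any(keep))
          res[[length(res) + 1]] <- data.frame(chrom = ch, start = s[keep],
                                               end = e[keep])
      }
    }
    if (!length(res)) return(empty[, 1:3])
    out <- do.call(rbind, res)
    out[order(out$chrom, out$start), , drop = FALSE]
  }
  acc <- sets[[1]][, c("chrom", "start", "end")]
  for (k in seq_along(sets)[-1]) {
    acc <- pair_intersect(acc, sets[[k]][, c("chrom", "start", "end")])
    if (nrow(acc) == 0) break
  }
  if (nrow(acc) == 0) return(empty)
  acc$sources <- paste(names(sets), collapse = ",")
  rownames(acc) <- NULL
  acc
}
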