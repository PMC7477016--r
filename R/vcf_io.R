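#' Read a phased, bi-allelic SNP VCF into the pipeline's matrices
#'
#' Parses a VCF 4.x file (plain or gzip) with `vcfR` and builds the three
#' internal containers used throughout the package: a site table, a diploid
#' dosage matrix and (for phased input) a haplotype matrix.  Non-bi-allelic
#' records and non-SNP records are dropped with a logged count.
#'
#' Ancestral alleles are taken from the `AA` INFO tag when present and valid
#' (equal to REF or ALT); otherwise the site falls back to REF-as-ancestral
#' and is flagged (`aa_fallback`), so that downstream scans can restrict
#' themselves to absolute scores where polarity is a guess.
#'
#' @param path Path to a VCF file (`.vcf` or `.vcf.gz`).
#' @param samples Optional character vector restricting to a sample subset.
#' @param region Optional `"chrom:start-end"` query, half-open on position
#'   (`start <= pos < end`, positions 1-based as stored).
#' @param haplotypes If `TRUE` (default) require fully phased, non-missing
#'   genotypes and build the haplotype matrix; unphased separators raise an
#'   error naming the first offending record.
#' @return An object of class `sweep_cohort`: a list with `sites` (data.frame
#'   chrom, pos, id, ref, alt, ancestral, aa_fallback), `geno` (samples x
#'   sites integer dosages 0/1/2, NA = missing), `haplo` (2N x sites 0/1
#'   matrix or NULL), `samples`, and `n_dropped` (records removed as
#'   non-bi-allelic/non-SNP).
#' @export
read_vcf <- function(path, samples = NULL, region = NULL, haplotypes = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (nrow(gt) == 0 || !"FORMAT" %in% colnames(gt)) stop("VCF has no genotype section")
  if (!all(startsWith(gt[, "FORMAT"], "GT"))) stop("GT must be the first FORMAT field")

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_dropped <- sum(!is_snp)
  if (n_dropped > 0)
    message("read_vcf: dropped ", n_dropped, " non-bi-allelic/non-SNP record(s)")

  keep <- which(is_snp)
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    inr <- chrom == m[2] & pos >= as.integer(m[3]) & pos < as.integer(m[4])
    keep <- keep[inr]; chrom <- chrom[inr]; pos <- pos[inr]
  }
  ord <- order(chrom, pos)
  keep <- keep[ord]; chrom <- chrom[ord]; pos <- pos[ord]
  if (anyDuplicated(cbind(chrom, pos)))
    stop("duplicate chrom:pos records after filtering")

  all_samples <- colnames(gt)[-1]
  if (is.null(samples)) samples <- all_samples
  missing_s <- setdiff(samples, all_samples)
  if (length(missing_s)) stop("samples not in VCF: ", paste(missing_s, collapse = ", "))

  g <- gt[keep, samples, drop = FALSE]
  # first (colon-separated) field is GT
  g <- sub(":.*$", "", g)

  id <- fix[keep, "ID"]
  id[id %in% c(".", "")] <- NA_character_
  info <- paste0(";", fix[keep, "INFO"])
  aa <- rep(NA_character_, length(keep))
  hasaa <- grepl(";AA=", info, fixed = TRUE)
  aa[hasaa] <- sub("^.*;AA=([^;]*).*$", "\\1", info[hasaa])
  refk <- fix[keep, "REF"]; altk <- fix[keep, "ALT"]
  aa[!is.na(aa) & aa != refk & aa != altk] <- NA_character_

  sites <- data.frame(
    chrom = chrom, pos = pos, id = id, ref = refk, alt = altk,
    ancestral = aa, aa_fallback = is.na(aa), stringsAsFactors = FALSE
  )

  n_site <- nrow(sites); n_samp <- length(samples)
  a1 <- substr(g, 1L, 1L); sep <- substr(g, 2L, 2L); a2 <- substr(g, 3L, 3L)
  is_miss <- a1 == "." | a2 == "." | g == "." | g == ""
  dos <- (a1 == "1") + (a2 == "1")
  dos[is_miss] <- NA_integer_
  geno <- matrix(as.integer(dos), nrow = n_samp, ncol = n_site, byrow = TRUE,
                 dimnames = list(samples, NULL))

  haplo <- NULL
  if (haplotypes) {
    bad <- which(sep == "/" & !is_miss)
    if (length(bad)) {
      i <- arrayInd(bad[1], dim(g))
      stop("unphased genotype at ", sites$chrom[i[1]], ":", sites$pos[i[1]],
           " sample ", samples[i[2]], " but phased output requested")
    }
    if (any(is_miss)) {
      i <- arrayInd(which(is_miss)[1], dim(g))
      stop("missing genotype at ", sites$chrom[i[1]], ":", sites$pos[i[1]],
           " sample ", samples[i[2]], " but phased output requested")
    }
    haplo <- matrix(0L, nrow = 2L * n_samp, ncol = n_site)
    haplo[seq(1, 2 * n_samp, by = 2), ] <- t(matrix(as.integer(a1 == "1"), n_site, n_samp))
    haplo[seq(2, 2 * n_samp, by = 2), ] <- t(matrix(as.integer(a2 == "1"), n_site, n_samp))
    attr(haplo, "sample_of_haplotype") <- rep(samples, each = 2)
  }

  structure(list(sites = sites, geno = geno, haplo = haplo,
                 samples = samples, n_dropped = n_dropped),
            class = "sweep_cohort")
}

#' Write a cohort back to VCF 4.2
#'
#' Emits phased `a|b` genotypes when the cohort carries haplotypes, otherwise
#' unphased dosage-derived genotypes.  The ancestral allele is written as the
#' `AA` INFO tag where known.  Output is gzip-compressed when `path` ends in
#' `.gz`.
#'
#' @param cohort A `sweep_cohort` as returned by [read_vcf()] or the
#'   simulator.
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  st <- cohort$sites
  n_samp <- length(cohort$samples)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )
  info <- ifelse(is.na(st$ancestral), ".", paste0("AA=", st$ancestral))
  if (!is.null(cohort$haplo)) {
    h1 <- cohort$haplo[seq(1, 2 * n_samp, by = 2), , drop = FALSE]
    h2 <- cohort$haplo[seq(2, 2 * n_samp, by = 2), , drop = FALSE]
    gtmat <- matrix(paste0(h1, "|", h2), nrow = n_samp)
  } else {
    gtmat <- matrix(c("0/0", "0/1", "1/1")[cohort$geno + 1L], nrow = n_samp)
    gtmat[is.na(cohort$geno)] <- "./."
  }
  body <- if (nrow(st) == 0) character(0) else
    paste(st$chrom, st$pos, ifelse(is.na(st$id), ".", st$id),
          st$ref, st$alt, ".", "PASS", info, "GT",
          apply(gtmat, 2, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a BED3/BED4 interval file
#'
#' Intervals are returned 0-based half-open (BED native), sorted by
#' (chrom, start); overlapping intervals are retained, not merged.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns chrom, start, end, name.
#' @export
read_intervals <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("malformed BED file: ", conditionMessage(e)))
  df <- as.data.frame(gr)
  out <- data.frame(
    chrom = as.character(df$seqnames),
    start = df$start - 1L,
    end = df$end,
    name = if ("name" %in% names(df)) as.character(df$name) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end))
    stop("malformed interval: start >= end at row ", which(out$start >= out$end)[1])
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write records as TSV or BED
#'
#' TSV output keeps the data.frame's column order with a header line; an
#' empty record set yields a header-only file.  BED output writes the
#' chrom/start/end (plus any further) columns without header; coordinates
#' are expected 0-based half-open, which is what all window operations in
#' this package produce.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(records))) stop("BED output needs chrom/start/end")
    ord <- c(need, setdiff(names(records), need))
    utils::write.table(records[, ord, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a sample-to-population assignment table
#'
#' Two-column TSV (sample, pop), with or without a header line.
#'
#' @param path Path to the TSV.
#' @return Named character vector: population label per sample id.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, col.names = c("sample", "pop"))
  if (identical(tolower(df$sample[1]), "sample")) df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df$sample)) stop("duplicate sample in population map")
  stats::setNames(df$pop, df$sample)
}

#' @export
print.sweep_cohort <- function(x, ...) {
  cat("sweep_cohort:", length(x$samples), "samples x", nrow(x$sites), "sites;",
      if (is.null(x$haplo)) "unphased" else "phased", "\n")
  invisible(x)
}
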