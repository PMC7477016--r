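#!/usr/bin/env Rscript
# Evidence integration: per-gene aggregates of |iHS|, Tajima's D, F_ST and
# xpEHH, the F_ST/xpEHH gates, the rank-sum score over the gated genes, and
# the interval intersection of the individual evidence tracks.

library(sweepscan)

genes <- read_intervals("results/sim/sweep/genes.bed")
ihs1 <- utils::read.delim("results/ihs_pop1.tsv")
xp <- utils::read.delim("results/xpehh.tsv")
td <- utils::read.delim("results/tajima_3kb_pop1.tsv")
fst <- utils::read.delim("results/fst_per_site.tsv")
truth <- jsonlite::read_json("results/sim/sweep/truth.json")

ev <- gene_evidence(genes, ihs1, xp, td, fst)
write_table(ev, "results/gene_evidence.tsv")

rk <- rank_genes(ev)
write_table(rk, "results/gene_rank.tsv")
truth_gene <- genes$name[genes$start <= truth$sweep_pos - 1 &
                           genes$end > truth$sweep_pos - 1]
message(sprintf("%d gene(s) pass the F_ST (top 5%%) and xpEHH (> 2.5) gates", nrow(rk)))
if (nrow(rk)) {
  print(rk[, c("gene", "ihs_max", "tajima_mean", "fst_mean", "xpehh_max",
               "rank_score")])
  message(sprintf("Top-ranked gene: %s (gene containing the planted sweep: %s)",
                  rk$gene[1], truth_gene))
}

# intersection of the per-track evidence intervals (gene bodies passing each
# single-statistic gate)
gate <- function(x, q) x >= stats::quantile(x, q, na.rm = TRUE)
tracks <- list(
  ihs = ev[!is.na(ev$ihs_max) & ev$ihs_max > 2, c("chrom", "start", "end")],
  xpehh = ev[!is.na(ev$xpehh_max) & ev$xpehh_max > 2.5, c("chrom", "start", "end")],
  fst = ev[!is.na(ev$fst_mean) & gate(ev$fst_mean, 0.95), c("chrom", "start", "end")],
  tajima = ev[!is.na(ev$tajima_mean) & gate(ev$tajima_mean, 0.75), c("chrom", "start", "end")]
)
inter <- intersect_evidence(tracks)
write_table(inter, "results/evidence_intersection.tsv")
message(sprintf("Intervals supported by all four evidence tracks: %d", nrow(inter)))
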