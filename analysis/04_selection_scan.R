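#!/usr/bin/env Rscript
# Haplotype-based selection scan on the sweep cohort: iHS in each
# population, cross-population xpEHH, 100 kb enrichment windows with the
# top-1% significance rule, gene annotation of the significant windows, and
# differential (POP1-not-POP2) candidate windows.

library(sweepscan)

co <- read_vcf("results/sweep_scanready.vcf")
pops <- read_popmap("results/sim/sweep/pops.tsv")
genes <- read_intervals("results/sim/sweep/genes.bed")
truth <- jsonlite::read_json("results/sim/sweep/truth.json")

h1 <- pop_haplotypes(co, pops, "POP1")
h2 <- pop_haplotypes(co, pops, "POP2")

ihs1 <- ihs_scan(h1, co$sites)
ihs2 <- ihs_scan(h2, co$sites)
write_table(ihs1, "results/ihs_pop1.tsv")
write_table(ihs2, "results/ihs_pop2.tsv")
message(sprintf("iHS: %d scan sites in POP1 (max |iHS| %.2f), %d in POP2",
                nrow(ihs1), max(ihs1$abs_ihs), nrow(ihs2)))

xp <- xpehh_scan(h1, h2, co$sites)
write_table(xp, "results/xpehh.tsv")
near <- abs(xp$pos - truth$sweep_pos) < 5e4
message(sprintf("xpEHH: max %.2f genome-wide, %.2f within 50 kb of the planted sweep",
                max(xp$xpehh), max(xp$xpehh[near])))

w <- bin_ihs(ihs1)
write_table(w, "results/ihs_windows_pop1.tsv")
sig <- w[w$significant, ]
write_table(sig[, c("chrom", "start", "end")], "results/sig_windows.bed",
            format = "bed")
sbin <- floor((truth$sweep_pos - 1) / 1e5) * 1e5
message(sprintf("Significant 100 kb windows: %s (sweep lies in [%d, %d): %s)",
                paste(sig$start, collapse = ", "), sbin, sbin + 1e5,
                if (sbin %in% sig$start) "recovered" else "missed"))

ann <- annotate_genes(sig, genes)
write_table(ann, "results/sig_window_genes.tsv")
message("Genes in significant windows: ", paste(unique(ann$gene), collapse = ", "))

cand <- candidate_sites(ihs1, ihs2)
write_table(cand$windows, "results/candidate_windows.tsv")
message(sprintf("Differential candidate windows (extreme in POP1, silent in POP2): %d",
                nrow(cand$windows)))
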