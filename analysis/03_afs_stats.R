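#!/usr/bin/env Rscript
# Allele-frequency statistics on the scan-ready sweep cohort:
# per-individual inbreeding F, 3 kb windowed Tajima's D in the sweep
# population, and per-site Weir-Cockerham F_ST between the two populations.

library(sweepscan)

co <- read_vcf("results/sweep_scanready.vcf")
pops <- read_popmap("results/sim/sweep/pops.tsv")

f <- inbreeding_f(co$geno)
write_table(data.frame(sample = names(f), pop = pops[names(f)], F = f),
            "results/inbreeding_f.tsv")
message(sprintf("Inbreeding F: mean %.4f (range %.3f .. %.3f)",
                mean(f), min(f), max(f)))

h1 <- pop_haplotypes(co, pops, "POP1")
td <- windowed_tajima_d(h1, co$sites, window_bp = 3000)
write_table(td, "results/tajima_3kb_pop1.tsv")
message(sprintf("Tajima's D (3 kb windows, POP1): mean %.3f over %d defined windows",
                mean(td$D, na.rm = TRUE), sum(!is.na(td$D))))

pc <- pop_allele_counts(co$geno, pops)
fst <- cbind(co$sites[, c("chrom", "pos")],
             wc_fst(pc$POP1$n, pc$POP1$ac, pc$POP2$n, pc$POP2$ac))
write_table(fst, "results/fst_per_site.tsv")
gw <- sum(fst$a, na.rm = TRUE) / sum(fst$a + fst$b + fst$c, na.rm = TRUE)
message(sprintf("Genome-wide F_ST (ratio of sums): %.4f", gw))

genes <- read_intervals("results/sim/sweep/genes.bed")
gene_fst <- region_mean_fst(fst, genes)
write_table(gene_fst, "results/fst_per_gene.tsv")
top <- gene_fst[order(-gene_fst$fst), ][1, ]
message(sprintf("Highest gene-level F_ST: %s (%.3f)", top$name, top$fst))
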