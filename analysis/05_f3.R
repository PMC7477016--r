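#!/usr/bin/env Rscript
# f3 admixture tests on the admixture cohort: is POP3 a mixture of POP1 and
# POP2?  The block jackknife gives the Z-score; strongly negative Z is
# evidence for admixture.

library(sweepscan)

co <- read_vcf("results/sim/admix/cohort.vcf")
pops <- read_popmap("results/sim/admix/pops.tsv")

rows <- list()
for (target in c("POP3", "POP1", "POP2")) {
  sources <- setdiff(unique(pops), target)
  r <- f3_from_cohort(co, pops, target, sources[1], sources[2],
                      block_span = 2.5e5)
  print(r)
  rows[[target]] <- data.frame(target = target, source_a = sources[1],
                               source_b = sources[2], f3 = r$f3, se = r$se,
                               z = r$z, n_snps = r$n_snps,
                               n_blocks = r$n_blocks)
}
write_table(do.call(rbind, rows), "results/f3_tests.tsv")
message("Expected pattern: only the admixed target (POP3) shows strongly negative Z.")
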