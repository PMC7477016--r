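#!/usr/bin/env Rscript
# Quality control of the sweep cohort: the full filtering cascade at both
# stages (population-genetic structure vs selection scan), with the per-step
# removal report written alongside the filtered data.

library(sweepscan)

co <- read_vcf("results/sim/sweep/cohort.vcf")
pops <- read_popmap("results/sim/sweep/pops.tsv")
message(sprintf("Input: %d samples x %d sites", length(co$samples),
                nrow(co$sites)))

for (stage in c("population", "scan")) {
  res <- apply_filter_cascade(co, filter_config(), stage = stage, pops = pops)
  write_table(res$report, sprintf("results/qc_report_%s.tsv", stage))
  message(sprintf("%s stage: %d sites survive", stage,
                  nrow(res$cohort$sites)))
  print(res$report)
  if (stage == "scan")
    write_vcf(res$cohort, "results/sweep_scanready.vcf")
}
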