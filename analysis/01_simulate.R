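#!/usr/bin/env Rscript
# Generate the three synthetic cohorts the downstream analyses use:
#   sweep/   two populations, hard sweep driven to high frequency in POP1
#   admix/   two sources plus a 50/50 pulse-admixed third population
#   neutral/ a single random-mating population
# Each directory gets a phased VCF, a population map, a truth record and a
# synthetic gene annotation.

library(sweepscan)

out <- "results/sim"

message("Simulating sweep cohort (N_e = 500, L = 1 Mb, s = 0.1) ...")
sweep <- simulate_cohort(sim_config(n_pops = 2, seed = 101, sweep = list()))
write_sim(sweep, file.path(out, "sweep"))
message(sprintf("  sweep at %d bp: frequency %.2f in POP1, %.2f in POP2 (%d generations, %d attempts)",
                sweep$truth$sweep_pos, sweep$truth$sweep_freq[1],
                sweep$truth$sweep_freq[2], sweep$truth$sweep_gens,
                sweep$truth$sweep_tries))

message("Simulating admixture cohort (alpha = 0.5 pulse into POP3) ...")
admix <- simulate_cohort(sim_config(
  n_pops = 2, N_e = 100, L = 3e6, mu = 4e-6, rec = 5e-8, split_gens = 100,
  admix = list(alpha = 0.5, time_gens = 5), n_samples = 50, seed = 202))
write_sim(admix, file.path(out, "admix"))
message(sprintf("  %d samples x %d sites", length(admix$cohort$samples),
                nrow(admix$cohort$sites)))

message("Simulating neutral panel ...")
neutral <- simulate_cohort(sim_config(n_pops = 1, seed = 303))
write_sim(neutral, file.path(out, "neutral"))
message(sprintf("  %d segregating sites", nrow(neutral$cohort$sites)))
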