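# Shared simulated fixtures, built lazily and cached for the whole run.

.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- build()
  .fx_cache[[name]]
}

# one neutral single-population panel at the default study scale
fx_neutral <- function() fx_get("neutral", function() {
  simulate_cohort(sim_config(n_pops = 1, seed = 77))
})

# small, fast two-population cohort for I/O and determinism checks
fx_small_cfg <- function(seed = 5) {
  sim_config(n_pops = 2, N_e = 60, L = 1e5, burn_gens = 500, split_gens = 20,
             n_samples = 10, seed = seed)
}
fx_small <- function() fx_get("small", function() simulate_cohort(fx_small_cfg()))

# default hard-sweep replicate (population 1 only)
fx_sweep <- function(i) fx_get(paste0("sweep", i), function() {
  simulate_cohort(sim_config(n_pops = 2, seed = 100 + i, sweep = list()))
})

toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
    "1\t100\t.\tA\tG\t.\tPASS\tAA=G\tGT\t0|1\t1|1",
    "1\t200\t.\tC\tG,T\t.\tPASS\t.\tGT\t0|1\t0|2",
    "1\t300\trs1\tT\tC\t.\tPASS\t.\tGT\t0|0\t0|1")
}
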