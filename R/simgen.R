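#' Simulation configuration
#'
#' Defines the synthetic study conditions: a forward-in-time Wright-Fisher
#' population of diploids with infinite-sites mutation and single-crossover
#' recombination, burned to mutation-drift equilibrium, optionally split
#' into two populations, with either a pulse-admixed third population or a
#' hard selective sweep confined to one population.
#'
#' Default rates are rescaled so that a deme of `N_e = 500` reproduces
#' a rescaled human model at desk scale: a scaling factor Q = 20 maps
#' N = 10000, mu = r = 1.25e-8 to `N_e = 500`, `mu = rec = 2.5e-7`,
#' preserving theta = 4 N mu (about 5e-4 per bp) and rho/theta = 1.  Default sampling
#' is 50 diploids per population, matching the scale of a single-population
#' sequencing cohort.  A default neutral split of 20 generations puts
#' two demes of 500 in the weak-differentiation regime (F_ST of roughly
#' 0.01-0.02); sweeps extend the split phase until the selected allele
#' reaches its end-condition frequency.
#'
#' @param n_pops 1 or 2 sampled populations (3 with admixture).
#' @param N_e Diploid effective size per population (ancestral deme uses
#'   the first value).
#' @param L Sequence length in bp.
#' @param mu,rec Per-bp per-generation mutation and recombination rates.
#' @param burn_gens Burn-in generations (default `6 * N_e`, several times
#'   the expected sample TMRCA, enough for a near-equilibrium frequency
#'   spectrum).
#' @param split_gens Generations between the split and sampling (neutral
#'   phase before the sweep, when one is configured).
#' @param admix `NULL` or `list(alpha =, time_gens =, N_e =, n_samples =)`:
#'   a third population formed `time_gens` generations before sampling by
#'   drawing each haplotype from population 1 with probability `alpha`,
#'   else population 2.
#' @param sweep `NULL` or `list(pop =, pos =, s =, start_copies =,
#'   end_freq =, max_tries =, max_gens =)`: additive hard sweep (fitness
#'   1, 1+s/2, 1+s) started from `start_copies` new copies (default 1) at
#'   `pos`, run until the selected allele reaches `end_freq` in `pop`;
#'   lost trajectories restart from the split state up to `max_tries`.
#' @param n_samples Diploids sampled per population.
#' @param seed Integer seed; same config + seed gives byte-identical VCFs.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2L, N_e = 500L, L = 1e6, mu = 2.5e-7,
                       rec = 2.5e-7, burn_gens = NULL, split_gens = 20L,
                       admix = NULL, sweep = NULL, n_samples = 50L,
                       seed = 1L) {
  if (any(c(mu, rec) < 0)) stop("rates must be >= 0")
  if (is.null(burn_gens)) burn_gens <- 6L * as.integer(N_e)
  if (!is.null(admix)) {
    admix <- utils::modifyList(
      list(alpha = 0.5, time_gens = 5L, N_e = N_e, n_samples = n_samples),
      admix)
    if (admix$alpha < 0 || admix$alpha > 1) stop("alpha must lie in [0, 1]")
    if (n_pops < 2) stop("admixture needs two source populations")
  }
  if (!is.null(sweep)) {
    # defaults: strongest sweep of the s = 0.05-0.1 regime, stopped at 0.9
    # (the highest frequency at which the core stays inside the scan's
    # MAF >= 0.05 ceiling), placed mid-bin so the 100 kb window grid does
    # not straddle the signal
    sweep <- utils::modifyList(
      list(pop = 1L, pos = round(0.55 * L), s = 0.1, start_copies = 1L,
           end_freq = 0.9, max_tries = 200L, max_gens = 5000L), sweep)
    if (!sweep$pop %in% seq_len(n_pops)) stop("sweep population must exist")
    if (!is.null(admix)) stop("sweep and admixture scenarios are separate")
  }
  structure(list(n_pops = as.integer(n_pops), N_e = as.integer(N_e), L = L,
                 mu = mu, rec = rec, burn_gens = as.integer(burn_gens),
                 split_gens = as.integer(split_gens), admix = admix,
                 sweep = sweep, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a phased cohort
#'
#' Runs the Wright-Fisher model of [sim_config()] and returns a phased
#' `sweep_cohort` (all populations' samples over the union of segregating
#' sites, derived alleles coded as ALT with the ancestral state in the AA
#' tag), the population map, and a truth record (realised sweep position
#' and per-population frequency, admixture fraction, split generations,
#' seed) for recovery tests.
#'
#' @param cfg A [sim_config()].
#' @return List with `cohort`, `pops` (named vector) and `truth`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  has_admix <- !is.null(cfg$admix)
  has_sweep <- !is.null(cfg$sweep)
  np_out <- cfg$n_pops + has_admix
  n_samples <- rep(cfg$n_samples, cfg$n_pops)
  if (has_admix) n_samples <- c(n_samples, cfg$admix$n_samples)
  ccfg <- list(
    L = cfg$L, mu = cfg$mu, rec = cfg$rec, N_anc = cfg$N_e,
    burn_gens = cfg$burn_gens, n_pops = cfg$n_pops,
    N1 = cfg$N_e, N2 = cfg$N_e, split_gens = cfg$split_gens,
    alpha = if (has_admix) cfg$admix$alpha else NA_real_,
    N3 = if (has_admix) as.integer(cfg$admix$N_e) else 0L,
    admix_gens = if (has_admix) as.integer(cfg$admix$time_gens) else 0L,
    sweep_pop = if (has_sweep) as.integer(cfg$sweep$pop) else 0L,
    sweep_pos = if (has_sweep) cfg$sweep$pos else 0,
    sweep_s = if (has_sweep) cfg$sweep$s else 0,
    sweep_copies = if (has_sweep) as.integer(cfg$sweep$start_copies) else 1L,
    sweep_end_freq = if (has_sweep) cfg$sweep$end_freq else 1,
    sweep_max_tries = if (has_sweep) as.integer(cfg$sweep$max_tries) else 1L,
    sweep_max_gens = if (has_sweep) as.integer(cfg$sweep$max_gens) else 0L,
    n_samples = as.integer(n_samples),
    cleanup_every = 8L
  )
  res <- wf_sim_cpp(ccfg)

  pop_names <- paste0("POP", seq_len(np_out))
  samples <- unlist(lapply(seq_len(np_out), function(pi)
    sprintf("%s_S%03d", pop_names[pi], seq_len(n_samples[pi]))))
  pops <- stats::setNames(rep(pop_names, n_samples), samples)

  hm <- do.call(rbind, res$haplotypes)
  storage.mode(hm) <- "integer"
  attr(hm, "sample_of_haplotype") <- rep(samples, each = 2)
  S <- length(res$positions)
  odd <- seq(1, nrow(hm), by = 2)
  gm <- hm[odd, , drop = FALSE] + hm[odd + 1, , drop = FALSE]
  rownames(gm) <- samples
  sites <- data.frame(chrom = rep("1", S), pos = as.integer(res$positions),
                      id = rep(NA_character_, S), ref = rep("A", S),
                      alt = rep("G", S), ancestral = rep("A", S),
                      aa_fallback = rep(FALSE, S), stringsAsFactors = FALSE)
  cohort <- structure(list(sites = sites, geno = gm, haplo = hm,
                           samples = samples, n_dropped = 0L),
                      class = "sweep_cohort")
  truth <- list(seed = cfg$seed, n_pops = np_out,
                split_gens = cfg$split_gens,
                sweep_pos = res$sweep_pos,
                sweep_freq = as.numeric(res$sweep_freq),
                sweep_s = if (has_sweep) cfg$sweep$s else NA_real_,
                sweep_gens = res$sweep_gens,
                sweep_tries = res$sweep_tries,
                alpha = if (has_admix) cfg$admix$alpha else NA_real_)
  list(cohort = cohort, pops = pops, truth = truth)
}

#' Synthetic gene grid
#'
#' A uniform annotation for simulated chromosomes: genes of `width` bp every
#' `spacing` bp starting at `offset` (0-based half-open), named gene001,
#' gene002, ...
#'
#' @param L Chromosome length in bp.
#' @param spacing,width,offset Grid layout in bp.
#' @param chrom Chromosome label.
#' @return data.frame in the [read_intervals()] layout.
#' @export
make_gene_grid <- function(L, spacing = 40000, width = 30000, offset = 5000,
                           chrom = "1") {
  starts <- seq(offset, L - width, by = spacing)
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(starts + width),
             name = sprintf("gene%03d", seq_along(starts)),
             stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Emits the phased VCF (`cohort.vcf`), the population map (`pops.tsv`),
#' the truth record (`truth.json`) and a synthetic gene grid (`genes.bed`).
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$cohort, file.path(dir, "cohort.vcf"))
  utils::write.table(data.frame(sample = names(sim$pops), pop = sim$pops),
                     file.path(dir, "pops.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  genes <- make_gene_grid(max(sim$cohort$sites$pos))
  write_table(genes, file.path(dir, "genes.bed"), format = "bed")
  invisible(dir)
}

#' Hand-checkable toy fixtures
#'
#' Small deterministic fixtures used across the unit tests:
#' \describe{
#'   \item{qc}{20 samples x 10 sites engineered so the filter cascade
#'     removes 2 (missingness) + 3 (minor allele count) + 1
#'     (Hardy-Weinberg) sites and keeps 4.}
#'   \item{ehh}{4 haplotypes \{00, 01, 10, 11\}.}
#'   \item{genes}{5 genes against 3 windows.}
#' }
#'
#' @return Named list of fixtures (`qc` is a `sweep_cohort`; `ehh` a list
#'   with `haps` and `positions`; `genes` a list with `genes` and
#'   `windows`).
#' @export
make_toy_fixtures <- function() {
  n <- 20L
  g <- matrix(0L, nrow = n, ncol = 10L)
  # sites 1-2: 3/20 = 15% missing -> removed by site missingness
  g[1:3, 1] <- NA; g[4:6, 2] <- NA
  g[, 1] <- ifelse(is.na(g[, 1]), NA, rep(c(0L, 1L), 10)[seq_len(n)])
  g[, 2] <- ifelse(is.na(g[, 2]), NA, rep(c(1L, 0L), 10)[seq_len(n)])
  # sites 3-5: minor allele count 1, 2, 0
  g[, 3] <- c(1L, rep(0L, n - 1))
  g[, 4] <- c(1L, 1L, rep(0L, n - 2))
  g[, 5] <- 0L
  # site 6: all heterozygous at p = 0.5 -> extreme HWE departure
  g[, 6] <- 1L
  # sites 7-10: well-behaved survivors
  g[, 7] <- rep(c(0L, 0L, 1L, 0L), 5)[seq_len(n)] + c(rep(0L, 18), 1L, 1L)
  g[, 8] <- c(rep(2L, 2), rep(1L, 6), rep(0L, 12))
  g[, 9] <- c(rep(2L, 1), rep(1L, 7), rep(0L, 12))
  g[, 10] <- c(rep(2L, 2), rep(1L, 8), rep(0L, 10))
  samples <- sprintf("S%02d", seq_len(n))
  rownames(g) <- samples
  qc <- structure(list(
    sites = data.frame(chrom = "1", pos = seq(1000L, by = 1000L, length.out = 10L),
                       id = NA_character_, ref = "A", alt = "G",
                       ancestral = "A", aa_fallback = FALSE,
                       stringsAsFactors = FALSE),
    geno = g, haplo = NULL, samples = samples, n_dropped = 0L),
    class = "sweep_cohort")

  ehh_toy <- list(
    haps = matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L), nrow = 4, byrow = TRUE),
    positions = c(1000, 2000))

  genes <- data.frame(
    chrom = "1",
    start = c(0L, 50000L, 120000L, 150000L, 290000L),
    end = c(30000L, 90000L, 140000L, 260000L, 310000L),
    name = paste0("g", 1:5), stringsAsFactors = FALSE)
  windows <- data.frame(chrom = "1", start = c(0L, 100000L, 200000L),
                        end = c(100000L, 200000L, 300000L))
  list(qc = qc, ehh = ehh_toy, genes = list(genes = genes, windows = windows))
}
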