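---
title: "Selection scans and population differentiation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans and population differentiation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sweepscan` implements a complete scan for recent positive selection and
population differentiation on phased, bi-allelic SNP data, together with a
forward-in-time Wright–Fisher simulator that generates phased cohorts with
known ground truth, so that every stage of the pipeline can be tested end to
end without access to any real genomes.  This vignette explains the models,
the tunable parameters, the numerical conventions, and what the synthetic
cohorts do and do not establish about behaviour on real data.

## Quality control

Filtering runs as an ordered cascade, because each step's removal count is
only meaningful given the sites that survived the previous step:

1. site missingness > 10%,
2. minor allele count < 3 (which also removes monomorphic sites),
3. minor allele frequency < 0.01,
4. Hardy–Weinberg exact p < 0.001,
5. individuals with > 10% missing genotypes (on the surviving sites),
6. a stage-specific step: LD thinning to pairwise r² < 0.1 for
   population-structure analyses, or a MAF ≥ 0.05 floor for selection scans.

The Hardy–Weinberg test is the standard exact test: all heterozygote counts
compatible with the observed allele counts are enumerated and the
probabilities of configurations no more likely than the observed one are
summed (two-sided by probability mass; no mid-p correction).  When a
population map is supplied the test runs per population and a site is
removed if it fails in any population — testing a pooled sample would
confound Hardy–Weinberg departures with the Wahlund effect; the pooled
variant remains available (`hwe_scope = "pooled"`).

LD thinning slides a 50-SNP window in steps of 5 along each chromosome and
drops the later-position member of any retained pair whose dosage r²
reaches 0.1, repeating until no removal occurs, which makes the operation
idempotent.  Missing dosages are mean-imputed inside the correlation
computation only and are never written to the output.  Window and step are
configurable; the defaults are the common pruning convention, since no
single choice is canonical.

## Allele-frequency statistics

**Inbreeding F** per individual is the method-of-moments estimator
`F = (O_hom − E_hom)/(L − E_hom)`, with the expected homozygosity summed
over the individual's called polymorphic sites as
`1 − 2p(1−p)·2n/(2n−1)` (`p` the sample allele frequency, `2n` the called
allele count at the site).  Sites with MAF 0 carry no information and are
excluded.

**Tajima's D** is computed in non-overlapping 3 kb windows tiling each
chromosome: `S` is the number of segregating sites in the window, π the
mean pairwise difference over haplotypes, and D their scaled difference
with the usual constants (a₁, a₂, b₁, b₂, c₁, c₂, e₁, e₂).  Windows with
`S = 0` are reported with an explicit missing D — never silently dropped
and never forced to zero — so that window counts stay auditable.  π is
taken from phased haplotypes when available.

**F_ST** uses the two-population Weir–Cockerham variance-components
estimator with phased alleles as sampling units: a between-population
component `a` and within-population component `b` from the one-way ANOVA
of the allele indicator, `fst = a/(a+b+c)` with `c = 0` in this layout.
Region means are ratio-of-sums, `Σa / Σ(a+b+c)`, the low-bias aggregation;
mean-of-ratios is available behind `method =` because published tables do
not always state which was used.  Per-site estimates at sites monomorphic
in both populations, or with fewer than two called alleles in either, are
explicit missing values; small negative per-site estimates are expected
under panmixia and are retained.

## Haplotype statistics

**EHH** at site *x* for a core site is the probability that two randomly
chosen haplotypes from the core set are identical at every site between
the core and *x*; the profile equals 1 at the core and is non-increasing
outward.  For allele-specific profiles the core set is the carriers of
that allele.  For the allele-agnostic profile used in cross-population
comparison, the denominator is the pair-homozygosity at the core itself,
which again normalises the profile to 1 at the core.

**iHH** integrates the EHH profile against physical distance (trapezoids),
each direction truncated at the first site where EHH drops below 0.05 with
the crossing point interpolated linearly, at any inter-SNP gap above
200 kb, or at the chromosome end.  Distances are physical base pairs
throughout; no genetic map is used.

**iHS** is `ln(iHH_ancestral / iHH_derived)`, standardised to mean 0 and
SD 1 within derived-allele-frequency bins of width 0.05, because the
neutral expectation of the log-ratio depends strongly on frequency.  Bins
with fewer than two sites fall back to pooled moments and are flagged.
Ancestral states come from the `AA` INFO tag; sites without a valid tag
fall back to reference-as-ancestral, are flagged, and should only be
interpreted through |iHS|.  Sites whose iHH is undefined on either allele
(fewer than two carriers, or a zero integral) are excluded with a logged
count.

**xpEHH** compares the allele-agnostic integrals between two populations
at the same site: `ln(iES_pop1 / iES_pop2)`, standardised genome-wide;
positive extremes mean longer haplotypes — candidate selection — in
population 1, and swapping the populations negates the raw score exactly.
Each population's profile is integrated to its own cutoff crossing by
default; a shared boundary taken from the pooled-population profile is
available (`boundary = "shared"`), since published descriptions of the
statistic differ on this point.

## Windowed sweep calling and evidence integration

The scan statistic for sweep regions is the fraction of SNPs with
|iHS| > 2 in non-overlapping 100 kb bins.  Bins with fewer than 20 SNPs
are excluded; among included bins, those whose fraction reaches the top
1% quantile are significant, with ties at the boundary all retained.  A
bin whose fraction is zero is never significant, which keeps a fully null
scan empty.  Differential candidates between two populations keep windows
with more than 20 extreme SNPs in the focal population that have no
counterpart window in the comparison population, with an optional
fixed-in-A-but-polymorphic-in-B frequency filter.

Per-gene evidence aggregates each statistic over the gene body: mean and
max |iHS|, extreme-SNP counts, mean Tajima's D over the overlapping 3 kb
bins (bin-overlap mean; the alternative of re-computing D from the SNPs
inside the gene is not used), ratio-of-sums F_ST, and max xpEHH.  Genes
passing an F_ST gate (top 5% quantile of gene-level means) and an xpEHH
gate (max > 2.5) are ranked best-first on Tajima's D mean, F_ST mean and
xpEHH max — larger values rank better on all three, ties get average
ranks — and the rank score is the sum of the three ranks, smallest first.
Ranks are computed among the gated candidates, which is the set the score
is meant to order.

## The synthetic cohort generator

The simulator is a discrete-generation Wright–Fisher model on binary
haplotypes: multinomial resampling of parents (fitness 1, 1+s/2, 1+s at a
single selected site, in the selected population only), infinite-sites
Poisson mutation with occupied positions re-drawn, single-crossover
recombination with probability `r·L` per meiosis at a uniform breakpoint,
population splits by copying, pulse admixture (each target haplotype drawn
from source 1 with probability α), and diploid sampling at output time.
All randomness flows through R's RNG, so a seed fixes the output to the
byte.

The default parameters form a rescaled human model: a scaling factor
Q = 20 maps N = 10,000 and μ = r = 1.25×10⁻⁸ per bp per generation onto
N_e = 500 and μ = r = 2.5×10⁻⁷, preserving θ = 4Nμ ≈ 5×10⁻⁴ per bp and
ρ/θ = 1.  A burn-in of 6·N_e generations — several times the expected
sample TMRCA — brings the frequency spectrum close to equilibrium: on a
neutral panel the mean windowed Tajima's D sits near −0.1 and the
|iHS| > 2 tail mass near 0.03–0.05, and mean inbreeding F is within
±0.01 of zero.  Fifty diploids are sampled per population, the scale of a
single-population sequencing cohort.

Scenario defaults: a neutral split of 20 generations puts two demes of
500 at F_ST ≈ 0.01, the weak-differentiation regime between closely
related populations, and split times of 50–100 generations reach ≈
0.05–0.09, so the 0.008–0.025 regime of interest is crossed from below.
The hard-sweep scenario uses s = 0.1 — the strong end of the
s = 0.05–0.1 range the recovery experiments target, and the
best-powered variant of that scenario — started from a single copy at
0.55·L (the centre of a 100 kb bin, so the window grid does not straddle
the signal) and run until the selected allele reaches frequency 0.9.
The end condition matters: the scan's MAF ≥ 0.05 floor removes sites with
derived frequency above 0.95, so a sweep driven beyond that point carries
its hitchhikers out of the scannable frequency range and the iHS signal
collapses; 0.9 is the highest "near fixation" end point at which the core
region remains observable.  Lost trajectories restart from the split
state up to a retry cap, and the realised position, frequency, duration
and attempt count are written to the truth record.  The f3 scenarios use
smaller, SNP-denser demes (N_e = 100, μ = 4×10⁻⁶, L = 2–3 Mb, ≈ 20–50k
SNPs) because the statistic needs many frequency observations rather than
haplotype structure, with jackknife blocks of 250 kb — well above the LD
scale of those simulations; the 5 Mb default block span is sized for real
genomes.

## What the synthetic data does and does not establish

The generator reproduces the statistical structure the methods consume —
drift-driven differentiation, admixture pulses with known α, hard sweeps
with known position and selection coefficient, equilibrium neutral
diversity — and therefore supports exact oracle tests, analytic limits,
sign conventions, determinism, and calibration of F_ST against split
time.  It does not emulate real-data features such as variable
recombination and mutation rate along the genome, sequencing and phasing
error, batch effects between sequencing depths, or realistic demographic
histories; passing tests on synthetic cohorts therefore validate the
implementation of the statistics, not their power on any particular real
cohort.

Desk scale also changes the power of the windowed recovery experiment
itself, in ways worth being explicit about.  At N_e = 500 and L = 1 Mb:
a replicate has only ten 100 kb bins, so the top-1% rule effectively asks
the sweep bin to be the argmax; the ancestral-allele class passes through
a severe absolute bottleneck during the sweep, so its surviving
haplotypes are often closely related, which randomly erases the
ln(iHH_A/iHH_D) contrast; and the sweep's own sites are a substantial
share of their frequency bins, so the within-bin standardisation absorbs
part of the signal that would stand out against a genome-wide background.
The planted sweep is recovered by the window rule in roughly six
replicates in ten, and the sweep gene ranks first in roughly half —
clear enrichment, but a recovery probability well below what the same
rule achieves at genome scale.  The cross-population xpEHH signal at the
sweep, by contrast, exceeds 2.5 in essentially every replicate, which is
the expected behaviour for sweeps near fixation: that contrast is exactly
what the statistic was designed for.

## Numerical conventions and degenerate inputs

* VCF positions are 1-based inclusive internally; all window arithmetic
  and BED output use 0-based half-open coordinates; region queries are
  half-open on position.
* Multi-allelic and non-SNP records are dropped with a logged count, not
  decomposed.
* Undefined statistics (D with S = 0, F_ST at doubly monomorphic sites,
  iHH with fewer than two carriers) are explicit `NA`s with logged
  counts.
* Ties: average ranks in gene ranking; ties at the top-1% window cutoff
  are all retained; the earlier-position site wins LD-pruning conflicts.
* The EHH cutoff (0.05), gap truncation (200 kb) and standardisation bin
  width (0.05) follow the conventions of the established haplotype-scan
  packages and are all configurable.
* Problem sizes in the tests and acceptance script (1 Mb chromosomes,
  12–20 replicates, three split times × three replicates) are chosen so
  the full suite runs on a single CPU at desk scale while leaving the
  Monte-Carlo bands meaningful.
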