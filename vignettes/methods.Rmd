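---
title: "Methods: inbreeding, diversity and composite selection scans in flockscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inbreeding, diversity and composite selection scans in flockscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockscan)
```

flockscan implements the within-population side of a livestock
SNP-array analysis: genotype quality control, runs-of-homozygosity (ROH)
inbreeding, Weir--Cockerham differentiation, LD-decay effective population
size, and a five-statistic decorrelated composite selection scan (DCMS).
This vignette records the models behind each stage, the defaults and the
reasoning behind the design choices that were genuinely open.

## Genotype model and quality control

Genotypes are diploid codes 0/1/2 counting copies of the `a2` allele, with
`NA` for missing calls. For text PLINK input the `a1` allele is the minor
allele computed at load time (ties resolved alphabetically); binary input
takes `a1` from the BIM file. All downstream frequency-based statistics
recompute allele frequencies after any filtering, so the orientation
choice never leaks into results.

`apply_qc()` applies the filters in a fixed order: samples with more than
10% missing calls are dropped first, then variants with more than 5%
missing calls *among the retained samples*, then non-autosomal variants
(sheep autosomes are labelled 1--26). Running the sample filter first
means a variant can be rescued by the removal of a bad sample; the report
records every removal with its missing rate. The order follows the
narrative convention of sample-then-variant filtering; PLINK's internal
order can differ in edge cases, which is why the report is explicit.

LD pruning (`ld_prune()`) mirrors `--indep-pairwise`: greedy removal
inside sliding windows, dropping from each linked pair the variant with
the lower minor allele frequency (ties: the later map position). The
tie-break makes the output deterministic for a given input ordering.

Relatedness filtering uses the off-diagonal of the Yang
variance-standardized genomic relationship matrix, computed within each
population, with a default threshold of 0.25. The estimator behind a
published "relatedness" value is often unstated; the GRM off-diagonal is
the choice here because the same matrix already underlies the F_GRM
inbreeding coefficient, and the threshold is an ordinary argument.

## ROH detection and inbreeding coefficients

`detect_roh()` reconstructs the PLINK `--homozyg` scanning logic: a
50-SNP window slides one SNP at a time; a window is a *hit* if it has no
heterozygous call and at most one missing call; a SNP is run-eligible if
at least 5% of the windows containing it are hits; maximal runs of
eligible, non-heterozygous SNPs are reported when they have at least
`min_snps` SNPs, span at least 1,000 kb, have at most 150 kb per SNP, and
contain no inter-SNP gap over 1,000 kb. The scanning-window size and the
5% hit threshold are not implied by the flag set that defines the other
parameters, so both are exposed as arguments with those defaults. A
consequence worth knowing: run boundaries are trimmed by roughly two SNPs
relative to a planted homozygous tract, because edge SNPs sit in too few
all-homozygous windows to pass the hit-proportion rule.

The minimum SNP count per run uses the L-parameter,
`L = ceiling(log(alpha/(n_snps * n_individuals)) / log(1 - mean_het))`,
clamped to at least 2. Ceiling is the conservative rounding: it can only
reduce chance runs below the nominal `alpha`.

Four inbreeding coefficients are reported per sample. F_ROH divides total
ROH length by the SNP-covered autosome (per-chromosome last minus first
SNP position plus one) rather than a fixed genome constant, so a run
tiling the covered chromosome gives exactly 1. F_GRM is the Yang GRM
diagonal minus one, F_HOM the excess-homozygosity form
`(O_hom - E_hom)/(m - E_hom)`, both over SNPs polymorphic within the
sample's population (monomorphic SNPs would divide by zero). F_IS is
population-level, `1 - mean(Ho_j)/mean(He_j)` over polymorphic SNPs,
because the heterozygosity ratio is a population quantity; single-sample
populations get `NA` with a warning.

## Differentiation and effective population size

`wc_fst()` implements the Weir--Cockerham (1984) two-population variance
components `a`, `b`, `c` with the full sample-size and heterozygosity
terms; the genome-wide mean is the ratio of sums `sum(a)/sum(a+b+c)`.
Negative estimates arise from sampling noise; per-SNP values are clamped
to zero for reporting and the mean is clamped independently, with the raw
values kept alongside so nothing is silently lost.

`ne_trajectory()` bins within-chromosome SNP pairs by distance (50 kb
bins from 50 kb to 4 Mb), averages the squared genotype correlation per
bin, subtracts the sample-size term `1/(beta*n)` (`beta = 2` for unphased
genotypes), and inverts `E[r2] = 1/(alpha + 4 Ne c)` with `alpha = 2` to
absorb mutation. The bin midpoint maps to recombination rate at a
constant 1 cM/Mb by default; the generation a bin informs is
`t = 1/(2c)`, rounded half-up so the 4 Mb bin reports 13 generations.
Two mapping functions are available: `linear` (identity) and
`sved_feldman`, the hyperbolic shrinkage `c = d/(1+2d)` used by LD-based
Ne tools to account for non-linearity between physical and genetic
distance at long range. Tests and the bundled experiments use `linear`,
which is exact for the simulator's uniform recombination. Whether to
apply the stringent 100/50/0.1 LD pruning before the Ne computation is
left to the caller: on a ~40k array it is affordable, but on the small
simulated panels used in the tests it would leave too few pairs per bin,
so the bundled experiments skip it.

## Selection statistics

All five statistics are computed within one population.

* **iHS** (`ihs_scan()`): `ln(iHH_A/iHH_D)` with iHH the trapezoid
  integral of EHH over physical distance, truncated where EHH falls below
  0.05; sites where EHH never reaches the cutoff before a chromosome end
  are reported missing rather than integrated over a censored curve.
  Scores are z-standardized within derived-allele-frequency bins of width
  0.05, per chromosome. Arrays carry no ancestral-state information, so
  allele 0 after `polarize_to_major()` (the dataset major allele) plays
  the ancestral role; this affects only the sign.
* **H12** (`h12_scan()`): haplotype frequencies in 25-SNP windows with
  the top two pooled, `(p1+p2)^2 + sum(p_i^2, i>=3)`.
* **ZHp** (`zhp_scan()`): pooled major/minor allele counts in 200 kb
  windows stepping 100 kb, `Hp = 2*M*m/(M+m)^2`, z-standardized over all
  windows genome-wide.
* **pi and Tajima's D** (`window_frequency_stats()`): allele-count forms
  in non-overlapping 300 kb windows, at least 10 SNPs per window. The
  allele-count form serves genotype and haplotype input identically.

## The DCMS composite

Native-resolution scores are assigned to non-overlapping 500 kb windows
by their midpoints (half-open intervals, so a midpoint exactly on a
boundary belongs to the following window) and averaged; the per-SNP
|iHS| series is median-smoothed (width 3) first, which is the one place
where smoothing has a clear target - isolated extreme sites. Each
statistic's window series is rank-transformed to tail-specific empirical
p-values with average-rank ties and an (N+1) denominator, which keeps p
strictly inside (0,1) without an arbitrary epsilon.

Default tails are right for iHS, H12 and pi and left for ZHp and Tajima's
D, matching how these statistics are conventionally reported in livestock
composite scans. A right tail for pi is surprising - sweeps *reduce*
diversity - so the sweep-detection experiments in the test suite pass
`pi = "left"` explicitly. All tails are arguments, none are hard-coded.

The composite is `DCMS_j = sum_i w_i log10((1-p_ij)/p_ij)` with
`w_i = 1/sum_k |r_ik|`, the correlations computed between p-value series
over pairwise-complete windows. Five perfectly correlated statistics
therefore collapse to the single-statistic score (weights 1/5 each): the
decorrelation contract. Windows with fewer than 3 of 5 components are
excluded; for windows missing some components the available weights are
rescaled to the full-set weight total, keeping scores comparable across
windows with different coverage. Calibration fits a normal distribution
to the scored windows (mean and SD), takes upper-tail p-values, and
applies Benjamini-Hochberg; windows with q < 0.05 are significant.
Significant windows, extended by 500 kb and merged, are exported as
0-based half-open BED records.

## The synthetic-genotype generator

`simulate_wf()` is a forward Wright-Fisher simulator: discrete
generations, diploid individuals, Poisson crossovers at a constant cM/Mb
rate, migration by parental-origin sampling, per-generation size
schedules, and two mating systems, selectable per population: random
mating, or persistent small flocks that mate within themselves except
for an occasional exchange of breeding animals (`flock_exchange`,
default 0.1 per offspring), emulating smallholder husbandry. The
exchange term matters: fully isolated ~10-animal flocks collapse to
near-complete autozygosity within tens of generations, stronger than
any real husbandry; a 10% exchange keeps F_ROH elevated but bounded.
All populations start from one ancestral frequency
pool drawn from a U-shaped Beta(1/2, 1/2) density, so divergence is
entirely drift and migration. Sites are ascertained at sampling time to
minor allele frequency >= 0.02 in the *pooled* sample across populations,
mimicking array design from a diversity panel: a site fixed in one
population stays on the array when other populations segregate for it.
This pooled ascertainment matters for selection scans - a completed sweep
erases exactly the within-population polymorphism a single-population
ascertainment would condition on.

Sweeps are planted at a chosen site with genotype fitnesses 1, 1+s,
1+2s. The default is a single copy (hard sweep de novo); `initial_copies
= k` plants k copies of *one founder haplotype*, a hard sweep from recent
standing variation that skips most of the stochastic establishment phase
and gives replicates comparable sweep durations; a fractional
`initial_freq` spreads the allele over random backgrounds (soft sweep).
Lost sweeps abort the attempt at the generation of loss and re-seed, up
to a retry cap, after which loss is reported honestly in the truth
record. `stop_at_freq` ends the run when the allele first reaches a
target frequency, capturing the population near fixation regardless of
the stochastic duration.

Test and experiment panels are genetically scaled-down genomes: 2-3
chromosomes of 10 Mb at 5-10 cM/Mb, i.e. 0.5-1 Morgan per chromosome,
standing in for ~100 Mb sheep chromosomes at 1 cM/Mb, with marker spacing
chosen so a 500 kb window holds SNP counts comparable to the real array's
~8 per window. Problem sizes in the bundled experiments (deme sizes
200-500, 100-800 generations, 30-80 samples) were chosen as the smallest
sizes at which the classical expectations they check (island-model FST,
LD-decay Ne recovery, sweep localization) have adequate power.

Two aspects of the sweep-detection panel (`sweep_panel_config()`)
deserve explanation. First, the sweep starts from one hundred copies of
a *single founder haplotype* rather than one copy: a sweep's haplotype
core narrows roughly as 1/(T c) with sweep duration T, so slow sweeps -
and single-copy sweeps have highly variable, often long durations -
erase their own localization signal. The single-origin standing-variation
start models a rapid recent sweep with uniform duration (~85-150
generations at s = 0.05) while remaining a hard sweep. Second, analysis
windows must scale with the panel's genetics: at 25 SNPs per window the
H12 statistic would span ~4 cM on this panel (versus ~0.4 cM on a real
50K array), far wider than the ~0.15 cM swept core, turning H12 into an
anti-signal; the experiment therefore uses 8-SNP H12 windows. Both the
experiment's tails (pi left) and the H12 window are explicit arguments,
and the package defaults remain the array-scale settings.

What the generator does *not* emulate: site-specific recombination and
mutation-rate variation, gene conversion, genotyping error, overlapping
generations, and real sheep demographic history. Passing tests therefore
show the estimators recover the parameters of an idealized Wright-Fisher
world, not that any particular real dataset is analysed correctly.

## Numerical choices and degenerate inputs

* Empirical p-values use (N+1) denominators and average ranks; an
  all-tied series maps to p = 0.5 everywhere.
* ZHp with zero variance across windows (every window identical) is an
  explicit error, as is DCMS calibration with fewer than 10 windows or
  zero score variance.
* Monomorphic SNPs are excluded from F_GRM/F_HOM denominators and from
  FST (when monomorphic in both populations jointly).
* Ne bins with no pairs, or with adjusted r2 so small that
  `1/r2 - alpha <= 0`, are emitted with missing Ne and flagged invalid.
* Coordinates are 1-based inclusive throughout, except BED export
  (0-based half-open); window arithmetic is half-open everywhere.
* `t = 1/(2c)` uses round-half-up so the boundary case lands on the
  more recent generation.

## Known limitations

The ROH scanner reproduces the hit-proportion logic of the reference
implementation but not its undocumented micro-optimisations; boundary
trimming of about two SNPs per run edge is expected. iHS on short
simulated chromosomes is frequently missing by construction (EHH cannot
decay below the cutoff within half a Morgan), so composite scans on such
panels run on the remaining four statistics. The Sved-Feldman mapping
formula follows the hyperbolic form used in the LD-Ne literature; tools
differ in this choice, which only matters beyond ~1 Mb distances.
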