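# Bundled parameter-recovery and calibration experiments. These drive the
# simulator through the full analysis stack and return the measured
# quantity next to its theoretical target, at problem sizes chosen to be
# the smallest with adequate power (see the methods vignette).

#' Island-model FST recovery experiment
#'
#' Simulates a two-deme Wright island model (deme size `N`, migrant-pool
#' rate `m`, so `4Nm = 5` with the defaults), runs Weir-Cockerham FST on
#' the sampled genotypes and returns it next to the equilibrium
#' approximation `1/(4Nm+1)`.
#'
#' @param N diploid deme size
#' @param m Wright migrant-pool rate
#' @param n_generations generations simulated
#' @param seed integer seed
#' @return list: `fst_observed`, `fst_expected`, `n_samples`
#' @export
island_fst_experiment <- function(N = 500, m = 0.0025,
                                  n_generations = 800, seed = 1) {
  cfg <- island_config(N = N, m = m, n_sample = 30,
                       n_generations = n_generations, n_chromosomes = 3,
                       chrom_length_bp = 5e6, snps_per_chrom = 120,
                       seed = seed)
  g <- simulate_wf(cfg)$genotypes
  list(fst_observed = wc_fst(g, "demeA", "demeB")$mean_fst,
       fst_expected = expected_island_fst(N, m),
       n_samples = n_samples(g))
}

#' Constant-size Ne recovery experiment
#'
#' Simulates a single constant-size population long enough for LD at
#' mid-range distances to equilibrate, runs the LD-decay Ne estimator
#' (linear mapping, no pruning - the simulated panel is sparse enough
#' already) and summarizes the mid-distance bins (1-3 Mb), whose
#' generation scale lies well inside the simulated history.
#'
#' @param N true diploid size
#' @param n_generations generations simulated
#' @param seed integer seed
#' @return list: `ne_median_mid_bins`, `ne_true`, `n_pairs`
#' @export
ne_recovery_experiment <- function(N = 200, n_generations = 200, seed = 1) {
  cfg <- wf_config(populations = list(list(label = "c", size = N,
                                           n_sample = 50)),
                   n_generations = n_generations, n_chromosomes = 3,
                   chrom_length_bp = 10e6, snps_per_chrom = 300, seed = seed)
  g <- simulate_wf(cfg)$genotypes
  tr <- ne_trajectory(g, mapping = "linear")
  mid <- tr[tr$dist_lo_bp >= 1e6 & tr$dist_hi_bp <= 3e6 & tr$valid, ]
  list(ne_median_mid_bins = stats::median(mid$Ne),
       ne_true = N, n_pairs = sum(mid$n_pairs))
}

#' Bottleneck Ne trajectory experiment
#'
#' Simulates a population that contracts (1000 to 100 diploids at
#' generation 60 of 120) and checks that the Ne trajectory declines
#' toward recent bins: recent bins (large distances) should estimate a
#' smaller Ne than older bins.
#'
#' @param seed integer seed
#' @return list: `ne_recent`, `ne_old`, `declining` (logical)
#' @export
bottleneck_ne_experiment <- function(seed = 1) {
  cfg <- wf_config(populations = list(list(
    label = "btl", size = c(rep(1000, 60), rep(100, 60)), n_sample = 40)),
    n_generations = 120, n_chromosomes = 3, chrom_length_bp = 10e6,
    snps_per_chrom = 300, seed = seed)
  g <- simulate_wf(cfg)$genotypes
  tr <- ne_trajectory(g, mapping = "linear")
  ok <- tr[tr$valid, ]
  recent <- ok[ok$t_generations <= 25, ]     # informed by the post-crash era
  old <- ok[ok$t_generations > 40, ]
  list(ne_recent = stats::median(recent$Ne),
       ne_old = stats::median(old$Ne),
       declining = stats::median(recent$Ne) < stats::median(old$Ne))
}

#' Run the composite scan of one sweep-panel replicate
#'
#' Runs the four window statistics (H12, ZHp, pi, Tajima's D; iHS is
#' mostly unscorable on genetically scaled panels and is exercised
#' separately) on the swept deme of a [sweep_panel_config()] simulation
#' and composes them with sweep-appropriate tails (pi left) and an H12
#' window of 8 SNPs, matching the panel's SNP density to the genetic
#' width of the swept core (see the methods vignette). Returns whether
#' the 500 kb window containing the sweep site attains the genome-wide
#' maximum DCMS.
#'
#' @param seed integer seed for the replicate
#' @param n_sample samples from the swept deme
#' @return list: `hit` (sweep window is the genome-wide max), `rank`
#'   (DCMS rank of the sweep window), `sweep_established`
#' @export
sweep_panel_replicate <- function(seed, n_sample = 60L) {
  s <- simulate_wf(sweep_panel_config(seed, n_sample = n_sample))
  gp <- subset_genotypes(s$genotypes,
                         samples = s$genotypes$samples$population == "swp")
  hp <- lapply(s$haplotypes, function(h)
    polarize_to_major(subset_haplotypes(h, gp$samples$sample_id))$haplotypes)
  dc <- dcms_pipeline(
    ihs = NULL, h12 = h12_scan(hp, window_snps = 8L),
    zhp = zhp_scan(gp, min_snps = 5),
    freq = window_frequency_stats(gp, min_snps = 5), min_components = 3,
    tails = c(ihs = "right", h12 = "right", zhp = "left", pi = "left",
              tajima_d = "left"))
  swpos <- s$truth$sweep$site_position_bp
  k <- which(dc$chrom == "1" & dc$start_bp <= swpos & dc$end_bp >= swpos)
  top <- dc[which.max(dc$dcms), ]
  list(hit = length(k) == 1 && top$chrom == "1" &&
         swpos >= top$start_bp && swpos <= top$end_bp,
       rank = if (length(k)) rank(-dc$dcms)[k] else NA_integer_,
       sweep_established = s$truth$sweep$established)
}

#' Null-calibration experiment
#'
#' Runs one neutral constant-size population through the same composite
#' scan as [sweep_panel_replicate()] and returns the fraction of windows
#' called significant at the given FDR - which should not exceed the
#' nominal level by more than simulation noise.
#'
#' @param seed integer seed
#' @param fdr_q FDR threshold
#' @return list: `significant_fraction`, `n_windows`
#' @export
null_scan_experiment <- function(seed, fdr_q = 0.05) {
  cfg <- wf_config(
    populations = list(list(label = "nul", size = 500, n_sample = 60),
                       list(label = "ref", size = 250, n_sample = 20)),
    n_generations = 120, n_chromosomes = 2, chrom_length_bp = 10e6,
    snps_per_chrom = 800, cm_per_mb = 8, seed = seed)
  s <- simulate_wf(cfg)
  gp <- subset_genotypes(s$genotypes,
                         samples = s$genotypes$samples$population == "nul")
  hp <- lapply(s$haplotypes, function(h)
    polarize_to_major(subset_haplotypes(h, gp$samples$sample_id))$haplotypes)
  dc <- dcms_pipeline(
    ihs = NULL, h12 = h12_scan(hp, window_snps = 8L),
    zhp = zhp_scan(gp, min_snps = 5),
    freq = window_frequency_stats(gp, min_snps = 5), min_components = 3,
    fdr_q = fdr_q,
    tails = c(ihs = "right", h12 = "right", zhp = "left", pi = "left",
              tajima_d = "left"))
  list(significant_fraction = mean(dc$significant), n_windows = nrow(dc))
}
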