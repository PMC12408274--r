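#' Configure a forward Wright-Fisher simulation
#'
#' Describes a multi-population diploid simulation with recombination,
#' migration, optional demographic change (per-generation size schedules),
#' small-flock mating and an optional hard sweep. All populations descend
#' from a common ancestral allele-frequency pool, so divergence accrues by
#' drift (and migration) alone.
#'
#' @param populations list of population descriptions; each a list with
#'   `label`, `size` (diploid size: scalar or per-generation vector),
#'   `n_sample` (individuals sampled at the end) and optionally `mating`,
#'   overriding the global mating system for that population
#' @param n_generations generations simulated forward
#' @param migration per-generation migration rate: scalar (symmetric rate
#'   applied between every ordered pair) or full matrix `m[i, k]` =
#'   probability an offspring of population i draws its parents from
#'   population k
#' @param n_chromosomes number of chromosomes (26 for a sheep-like genome)
#' @param chrom_length_bp chromosome length in bp
#' @param snps_per_chrom candidate SNP sites simulated per chromosome
#'   (post-ascertainment counts are lower)
#' @param spacing `"uniform"` (even grid) or `"jittered"` (grid with
#'   uniform jitter, array-like irregular spacing)
#' @param sweep optional list: `population`, `chromosome`, `position_bp`,
#'   `s` (selection coefficient; fitnesses 1, 1+s, 1+2s),
#'   `start_generation`, `initial_freq` (`NULL`, the default, plants a
#'   single copy - a hard sweep de novo; a positive fraction plants
#'   standing variation on that share of gametes, giving a soft sweep),
#'   `initial_copies` (alternative to `initial_freq`: plant this many
#'   copies of ONE founder haplotype, a hard sweep from recent standing
#'   variation that skips most of the stochastic establishment phase), and
#'   optional `stop_at_freq`: end the simulation as soon as the sweep
#'   allele reaches this frequency, capturing the population near fixation
#'   irrespective of the stochastic sweep duration
#' @param mating `"random"`, or `"small_flock"` with `flock_size`:
#'   populations are partitioned into persistent flocks and mating occurs
#'   within flock, emulating smallholder husbandry and elevating
#'   autozygosity
#' @param flock_size diploid individuals per flock for small-flock mating
#' @param flock_exchange per-offspring probability that the parents are
#'   drawn from a different, randomly chosen flock (breeding-animal
#'   exchange; keeps flock lines from collapsing into full autozygosity)
#' @param maf_min array-ascertainment threshold: sites below this minor
#'   allele frequency in the final sample are discarded (default 0.02)
#' @param cm_per_mb recombination rate (default 1 cM/Mb)
#' @param seed mandatory integer seed
#' @return list of class `wf_config`
#' @export
wf_config <- function(populations, n_generations, migration = 0,
                      n_chromosomes = 3L, chrom_length_bp = 10e6,
                      snps_per_chrom = 200L,
                      spacing = c("jittered", "uniform"), sweep = NULL,
                      mating = c("random", "small_flock"), flock_size = 10L,
                      flock_exchange = 0.1, maf_min = 0.02, cm_per_mb = 1.0,
                      seed) {
  spacing <- match.arg(spacing)
  mating <- match.arg(mating)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(flock_exchange >= 0, flock_exchange < 1)
  npop <- length(populations)
  for (p in populations) {
    stopifnot(!is.null(p$label), all(p$size >= 2), p$n_sample >= 1)
    if (!is.null(p$mating))
      stopifnot(p$mating %in% c("random", "small_flock"))
  }
  if (is.matrix(migration)) {
    stopifnot(nrow(migration) == npop, ncol(migration) == npop,
              all(migration >= 0), all(migration < 1))
    M <- migration; diag(M) <- 0
  } else {
    stopifnot(migration >= 0, migration < 1)
    M <- matrix(migration, npop, npop); diag(M) <- 0
  }
  if (!is.null(sweep)) {
    stopifnot(!is.null(sweep$population), !is.null(sweep$chromosome),
              !is.null(sweep$position_bp), sweep$s >= 0)
    if (is.null(sweep$start_generation)) sweep$start_generation <- 1L
  }
  structure(list(populations = populations, n_generations = n_generations,
                 migration = M, n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = chrom_length_bp,
                 snps_per_chrom = as.integer(snps_per_chrom),
                 spacing = spacing, sweep = sweep, mating = mating,
                 flock_size = as.integer(flock_size),
                 flock_exchange = flock_exchange, maf_min = maf_min,
                 cm_per_mb = cm_per_mb, seed = as.integer(seed)),
            class = "wf_config")
}

# one recombinant gamete from a parent's two haplotype rows
recombine <- function(h1, h2, pos, len_bp, morgans) {
  n_x <- stats::rpois(1, morgans)
  use1 <- stats::runif(1) < 0.5
  if (n_x == 0) return(if (use1) h1 else h2)
  xpos <- sort(stats::runif(n_x, 0, len_bp))
  seg <- findInterval(pos, xpos)          # segment index per site
  take2 <- (seg %% 2L == 0L) != use1
  out <- h1
  out[take2] <- h2[take2]
  out
}

pop_size_at <- function(size, g) {
  if (length(size) == 1) size else size[min(g, length(size))]
}

#' Run a forward Wright-Fisher simulation
#'
#' Simulates the configured populations forward in time and returns the
#' sampled, array-ascertained dataset: unphased genotype codes, the
#' truth-phased haplotypes per chromosome, and a truth record (realized
#' sweep-allele trajectory, final allele frequencies, configuration echo).
#' When the sweep allele is lost, the sweep is re-seeded with a shifted
#' stream up to `sweep_retries` times, after which it is reported as lost.
#'
#' @param config a [wf_config()] object
#' @param sweep_retries re-seeding attempts for a lost sweep allele (a
#'   single-copy sweep is usually lost to drift; attempts that lose the
#'   allele are abandoned as soon as the loss occurs)
#' @return list with `genotypes` (a `genotype_matrix`), `haplotypes`
#'   (list of `haplotype_set`, one per chromosome, allele 1 = the
#'   simulated alternate allele) and `truth` (list)
#' @export
simulate_wf <- function(config, sweep_retries = 50L) {
  stopifnot(inherits(config, "wf_config"))
  attempt <- 0L
  repeat {
    abortable <- !is.null(config$sweep) && attempt < sweep_retries
    res <- simulate_wf_once(config, config$seed + attempt * 997L,
                            abort_on_loss = abortable)
    if (is.null(config$sweep) ||
        (!isTRUE(res$aborted) && res$truth$sweep$established) ||
        attempt >= sweep_retries) {
      if (isTRUE(res$aborted))      # cap reached while aborting: full rerun
        res <- simulate_wf_once(config, config$seed + attempt * 997L,
                                abort_on_loss = FALSE)
      res$truth$sweep_attempts <- attempt + 1L
      return(res)
    }
    attempt <- attempt + 1L
  }
}

simulate_wf_once <- function(config, seed, abort_on_loss = FALSE) {
  set.seed(seed)
  npop <- length(config$populations)
  labels <- vapply(config$populations, `[[`, "", "label")
  nchr <- config$n_chromosomes
  len <- config$chrom_length_bp
  m <- config$snps_per_chrom
  morgans <- len / 1e6 * config$cm_per_mb / 100   # map length per chromosome

  # SNP positions per chromosome
  positions <- lapply(seq_len(nchr), function(ch) {
    grid <- seq(len / (2 * m), len - len / (2 * m), length.out = m)
    if (config$spacing == "jittered") {
      jit <- stats::runif(m, -0.4, 0.4) * (len / m)
      grid <- sort(grid + jit)
      grid <- pmin(pmax(round(grid), 1), len)
      grid <- unique(grid)
    } else grid <- round(grid)
    grid
  })

  # ancestral frequencies: U-shaped density shared by all populations
  anc_p <- lapply(positions, function(p) stats::rbeta(length(p), 0.5, 0.5))

  # state: H[[pop]][[chr]] = 2N x m matrix
  H <- vector("list", npop)
  for (i in seq_len(npop)) {
    N0 <- pop_size_at(config$populations[[i]]$size, 1)
    H[[i]] <- lapply(seq_len(nchr), function(ch)
      matrix(stats::rbinom(2 * N0 * length(anc_p[[ch]]), 1,
                           rep(anc_p[[ch]], each = 2 * N0)),
             nrow = 2 * N0))
  }
  pop_mating <- vapply(config$populations, function(p)
    if (is.null(p$mating)) config$mating else p$mating, "")
  flocks <- vector("list", npop)
  for (i in seq_len(npop))
    if (pop_mating[i] == "small_flock") {
      N0 <- pop_size_at(config$populations[[i]]$size, 1)
      flocks[[i]] <- ((seq_len(N0) - 1L) %/% config$flock_size) + 1L
    }

  sw <- config$sweep
  sw_pop <- sw_chr <- sw_site <- NA_integer_
  sw_traj <- numeric()
  if (!is.null(sw)) {
    sw_pop <- match(sw$population, labels)
    if (is.na(sw_pop)) stop("sweep population not found: ", sw$population)
    sw_chr <- sw$chromosome
    sw_site <- which.min(abs(positions[[sw_chr]] - sw$position_bp))
  }

  for (g in seq_len(config$n_generations)) {
    # plant the sweep allele as standing variation at its start generation
    if (!is.null(sw) && g == sw$start_generation) {
      n_g <- nrow(H[[sw_pop]][[sw_chr]])
      if (!is.null(sw$initial_copies) && sw$initial_copies > 1) {
        # k copies of one founder haplotype: hard sweep, short stochastic phase
        k <- min(sw$initial_copies, n_g)
        picked <- sample.int(n_g, k)
        H[[sw_pop]][[sw_chr]][, sw_site] <- 0L
        founder <- H[[sw_pop]][[sw_chr]][picked[1], ]
        founder[sw_site] <- 1L
        H[[sw_pop]][[sw_chr]][picked, ] <-
          matrix(founder, k, length(founder), byrow = TRUE)
      } else {
        k <- if (is.null(sw$initial_freq)) 1L
             else max(1L, round(n_g * sw$initial_freq))
        carriers <- sample.int(n_g, k)
        H[[sw_pop]][[sw_chr]][, sw_site] <- 0L
        H[[sw_pop]][[sw_chr]][carriers, sw_site] <- 1L
      }
    }
    newH <- vector("list", npop)
    new_flocks <- vector("list", npop)
    for (i in seq_len(npop)) {
      Nn <- pop_size_at(config$populations[[i]]$size, g + 1)
      # source population per offspring (migration by parental origin)
      mrow <- config$migration[i, ]
      probs <- c(1 - sum(mrow), mrow)
      src <- sample.int(npop + 1L, Nn, replace = TRUE, prob = probs)
      src <- ifelse(src == 1L, i, src - 1L)
      newH[[i]] <- lapply(seq_len(nchr), function(ch)
        matrix(0L, 2 * Nn, length(positions[[ch]])))
      if (pop_mating[i] == "small_flock")
        new_flocks[[i]] <- integer(Nn)
      for (o in seq_len(Nn)) {
        sp <- src[o]
        Ns <- nrow(H[[sp]][[1]]) / 2
        # parent sampling weights: sweep fitness, within-flock restriction
        wts <- rep(1, Ns)
        if (!is.null(sw) && sp == sw_pop && g >= sw$start_generation) {
          x <- H[[sp]][[sw_chr]][2 * seq_len(Ns) - 1, sw_site] +
               H[[sp]][[sw_chr]][2 * seq_len(Ns), sw_site]
          wts <- 1 + sw$s * x
        }
        if (pop_mating[i] == "small_flock" && sp == i) {
          # offspring inherits a flock; parents come from that flock, or
          # from a randomly chosen other flock when breeding animals are
          # exchanged
          fl <- flocks[[i]][((o - 1L) %% length(flocks[[i]])) + 1L]
          breed_fl <- fl
          n_fl <- max(flocks[[i]])
          if (n_fl > 1 && stats::runif(1) < config$flock_exchange)
            breed_fl <- sample.int(n_fl, 1)
          wts[flocks[[sp]] != breed_fl] <- 0
          new_flocks[[i]][o] <- fl
        } else if (pop_mating[i] == "small_flock") {
          new_flocks[[i]][o] <- flocks[[i]][((o - 1L) %% length(flocks[[i]])) + 1L]
        }
        if (sum(wts > 0) >= 2) {
          par <- sample.int(Ns, 2, replace = FALSE, prob = wts)
        } else {
          par <- rep(which(wts > 0)[1], 2)
          if (is.na(par[1])) par <- sample.int(Ns, 2, replace = Ns < 2)
        }
        for (ch in seq_len(nchr)) {
          pos <- positions[[ch]]
          newH[[i]][[ch]][2 * o - 1, ] <-
            recombine(H[[sp]][[ch]][2 * par[1] - 1, ],
                      H[[sp]][[ch]][2 * par[1], ], pos, len, morgans)
          newH[[i]][[ch]][2 * o, ] <-
            recombine(H[[sp]][[ch]][2 * par[2] - 1, ],
                      H[[sp]][[ch]][2 * par[2], ], pos, len, morgans)
        }
      }
    }
    H <- newH
    for (i in seq_len(npop))
      if (pop_mating[i] == "small_flock") flocks[[i]] <- new_flocks[[i]]
    if (!is.null(sw) && g >= sw$start_generation) {
      fq <- mean(H[[sw_pop]][[sw_chr]][, sw_site])
      sw_traj <- c(sw_traj, fq)
      if (abort_on_loss && fq == 0)
        return(list(aborted = TRUE,
                    truth = list(sweep = list(established = FALSE))))
      if (!is.null(sw$stop_at_freq) && fq >= sw$stop_at_freq) break
    }
  }

  # sample individuals and assemble output
  samp <- lapply(seq_len(npop), function(i) {
    N <- nrow(H[[i]][[1]]) / 2
    sort(sample.int(N, min(config$populations[[i]]$n_sample, N)))
  })
  ids <- unlist(lapply(seq_len(npop), function(i)
    sprintf("%s_%03d", labels[i], seq_along(samp[[i]]))))
  pops <- unlist(lapply(seq_len(npop), function(i)
    rep(labels[i], length(samp[[i]]))))

  hsets <- list()
  for (ch in seq_len(nchr)) {
    rows <- do.call(rbind, lapply(seq_len(npop), function(i) {
      r <- as.vector(rbind(2 * samp[[i]] - 1, 2 * samp[[i]]))
      H[[i]][[ch]][r, , drop = FALSE]
    }))
    # array-like ascertainment on the pooled sample
    freq <- colMeans(rows)
    keep <- pmin(freq, 1 - freq) >= config$maf_min
    hsets[[ch]] <- haplotype_set(as.character(ch), positions[[ch]][keep],
                                 rows[, keep, drop = FALSE], ids)
  }
  names(hsets) <- as.character(seq_len(nchr))
  geno <- haplotypes_to_genotypes(hsets, stats::setNames(pops, ids))

  final_freq <- if (!is.null(sw)) mean(H[[sw_pop]][[sw_chr]][, sw_site])
                else NA_real_
  truth <- list(
    seed_used = seed,
    labels = labels,
    n_sampled = vapply(samp, length, 0L),
    sweep = if (is.null(sw)) list(present = FALSE) else list(
      present = TRUE, population = sw$population, chromosome = sw_chr,
      site_position_bp = positions[[sw_chr]][sw_site],
      s = sw$s, final_freq = final_freq,
      trajectory = sw_traj,
      established = is.finite(final_freq) && final_freq >= 0.5))
  list(genotypes = geno, haplotypes = hsets, truth = truth)
}

#' Hard-sweep detection panel
#'
#' The standard configuration of the sweep-detection experiment: a swept
#' deme and a neutral reference deme (whose samples keep swept sites on
#' the simulated array through pooled ascertainment), two chromosomes of
#' 10 Mb at 8 cM/Mb - a genetically scaled-down genome whose sweep
#' footprint matches the 500 kb analysis windows - and a hard sweep
#' (s = 0.05) on the first chromosome from one hundred copies of a single
#' founder haplotype (single-origin standing variation; slow sweeps erode
#' their own haplotype core, so the panel models a rapid recent sweep),
#' captured when the allele first reaches 95\% frequency. The second
#' chromosome is the neutral control.
#'
#' @param seed integer seed
#' @param n_sample samples drawn from the swept deme
#' @return a `wf_config`
#' @export
sweep_panel_config <- function(seed, n_sample = 60L) {
  wf_config(
    populations = list(list(label = "swp", size = 500, n_sample = n_sample),
                       list(label = "ref", size = 250, n_sample = 20)),
    n_generations = 340, n_chromosomes = 2, chrom_length_bp = 10e6,
    snps_per_chrom = 800, cm_per_mb = 8,
    sweep = list(population = "swp", chromosome = 1, position_bp = 5.25e6,
                 s = 0.05, start_generation = 1, initial_copies = 100,
                 stop_at_freq = 0.95),
    seed = seed)
}

#' Island-model equilibrium FST approximation
#'
#' Classic expectation for two demes of diploid size `N` exchanging
#' migrants at rate `m` per generation: `FST ~ 1 / (4 N m + 1)`.
#'
#' @param N diploid deme size
#' @param m per-generation migration rate (`N * m > 0`)
#' @return approximate equilibrium FST
#' @export
expected_island_fst <- function(N, m) 1 / (4 * N * m + 1)

#' Flip haplotype coding so allele 0 is the major allele
#'
#' iHS polarization helper: columns where the 1 allele is in the majority
#' across the supplied gametes are flipped, so that allele 0 plays the
#' ancestral role.
#'
#' @param h a `haplotype_set`
#' @return list: `haplotypes` (recoded `haplotype_set`), `flipped`
#'   (logical per site)
#' @export
polarize_to_major <- function(h) {
  f <- colMeans(h$haplotypes)
  flip <- f > 0.5
  H <- h$haplotypes
  H[, flip] <- 1L - H[, flip]
  list(haplotypes = haplotype_set(h$chrom, h$positions_bp, H, h$sample_ids),
       flipped = flip)
}

#' Build a named deterministic fixture dataset
#'
#' Writes one of the bundled test datasets to `dir`: PLINK text files, a
#' phased VCF where phase is meaningful, and a JSON truth manifest. All
#' fixtures are generated in code with fixed seeds, never shipped as data.
#'
#' * `tiny_qc` - 10 samples x 100 SNPs with planted missingness crossing
#'   the 0.10 / 0.05 call-rate thresholds.
#' * `roh_runs` - one individual with planted homozygous tracts of 3, 7,
#'   12, 18 and 25 Mb (one per length class) on separate chromosomes.
#' * `sweep_panel` - 30 simulated samples; chromosome 1 carries a completed
#'   s = 0.05 sweep at its centre, chromosome 2 is a neutral control.
#' * `two_pop_fst` - two demes, diploid size 500, symmetric migration with
#'   4Nm = 5.
#' * `bottleneck_ne` - one population contracting 1000 -> 100.
#'
#' @param name fixture name
#' @param dir output directory (created if needed)
#' @param seed base seed for the simulated fixtures
#' @return list: `prefix` (PLINK path prefix), `vcf` (path or NA),
#'   `manifest` (path), `truth` (list)
#' @export
make_fixture <- function(name, dir = tempfile("fixture_"), seed = 20260101) {
  options_ <- c("tiny_qc", "roh_runs", "sweep_panel", "two_pop_fst",
                "bottleneck_ne")
  if (!name %in% options_)
    stop("unknown fixture '", name, "'; options: ",
         paste(options_, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- file.path(dir, name)
  vcf <- NA_character_
  set.seed(seed)
  if (name == "tiny_qc") {
    n <- 10; m <- 100
    calls <- matrix(stats::rbinom(n * m, 2, 0.4), n, m)
    calls[1, 1:11] <- NA          # 11% missing -> removed at mind 0.10
    calls[3, 1:15] <- NA          # 15% missing -> removed
    # variant 50: missing in 1 of the 8 retained samples (12.5% > 5%)
    calls[5, 50] <- NA
    truth <- list(removed_samples = c("s01", "s03"),
                  removed_variants = "v050",
                  n_samples_out = 8, n_variants_out = 99)
    g <- genotype_matrix(calls,
      data.frame(sample_id = sprintf("s%02d", 1:n), population = "tiny"),
      data.frame(chrom = "1", pos_bp = seq(1e5, by = 1e5, length.out = m),
                 id = sprintf("v%03d", 1:m), a1 = "A", a2 = "B"))
    save_plink(g, prefix, "text")
  } else if (name == "roh_runs") {
    lens_mb <- c(3, 7, 12, 18, 25)
    spacing <- 5e4                  # 50 kb: even the 3 Mb tract holds 60 SNPs
    n_other <- 9
    vars <- NULL; tracts <- list()
    tract_snps <- lens_mb * 20
    for (ch in seq_along(lens_mb)) {
      m_ch <- tract_snps[ch] + 160                # 80 flanking SNPs per side
      vars <- rbind(vars, data.frame(
        chrom = as.character(ch),
        pos_bp = seq(spacing, by = spacing, length.out = m_ch),
        id = sprintf("c%d_v%03d", ch, 1:m_ch), a1 = "A", a2 = "B"))
    }
    m <- nrow(vars)
    calls <- matrix(stats::rbinom((n_other + 1) * m, 2, 0.5), n_other + 1, m)
    # sample 1: heterozygous background, homozygous planted tracts
    calls[1, ] <- 1L
    for (ch in seq_along(lens_mb)) {
      k <- which(vars$chrom == as.character(ch))
      idx <- k[81:(80 + tract_snps[ch])]
      calls[1, idx] <- 2L
      tracts[[ch]] <- list(chrom = as.character(ch),
                           start_bp = vars$pos_bp[idx[1]],
                           end_bp = vars$pos_bp[idx[length(idx)]],
                           n_snps = tract_snps[ch])
    }
    truth <- list(sample_with_runs = "r01", planted_mb = lens_mb,
                  spacing_bp = spacing, tracts = tracts)
    g <- genotype_matrix(calls,
      data.frame(sample_id = sprintf("r%02d", 1:(n_other + 1)),
                 population = "rohpop"), vars)
    save_plink(g, prefix, "text")
  } else {
    cfg <- switch(name,
      sweep_panel = sweep_panel_config(seed),
      two_pop_fst = island_config(
        N = 500, m = 0.0025, n_sample = 30, n_generations = 800,
        n_chromosomes = 3, chrom_length_bp = 5e6, snps_per_chrom = 120,
        seed = seed),
      bottleneck_ne = wf_config(
        populations = list(list(
          label = "btl", size = c(rep(1000, 60), rep(100, 60)),
          n_sample = 40)),
        n_generations = 120, n_chromosomes = 3, chrom_length_bp = 10e6,
        snps_per_chrom = 300, seed = seed))
    sim <- simulate_wf(cfg)
    save_plink(sim$genotypes, prefix, "text")
    vcf <- paste0(prefix, ".vcf")
    write_phased_vcf(sim$haplotypes, vcf)
    truth <- sim$truth
  }
  manifest <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(truth, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(prefix = prefix, vcf = vcf, manifest = manifest, truth = truth)
}
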