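test_that("L parameter reproduces the reference arithmetic and clamps", {
  expect_equal(l_parameter(39685, 238, 0.05, mean_het = 0.35), 45L)
  # alpha / (ns * ni) >= 1 collapses to the minimum of 2
  expect_equal(l_parameter(1, 1, alpha = 1, mean_het = 0.3), 2L)
  expect_error(l_parameter(100, 10, mean_het = 0), "mean_het")
  expect_error(l_parameter(100, 10, mean_het = 1), "mean_het")
  # lower heterozygosity means chance runs are likelier, so L must grow
  hets <- seq(0.05, 0.6, by = 0.05)
  Ls <- vapply(hets, function(h) l_parameter(4e4, 200, mean_het = h), 0L)
  expect_true(all(diff(Ls) <= 0))
})

test_that("an all-heterozygous sample yields no ROH", {
  g <- make_geno(matrix(1L, 2, 100))
  segs <- detect_roh(g, roh_params(min_snps = 10))
  expect_equal(nrow(segs), 0)
})

test_that("a planted homozygous tract is called once, and a long gap
           splits it", {
  n_snp <- 100
  pos <- seq(30e3, by = 30e3, length.out = n_snp)   # spans 2.97 Mb + 30 kb
  calls <- rbind(c(rep(1L, 0), rep(0L, n_snp)))     # all homozygous
  other <- matrix(1L, 3, n_snp)                     # het background samples
  g <- make_geno(rbind(calls, other), pos = pos)
  segs <- detect_roh(g, roh_params(min_snps = 50))
  segs <- segs[segs$sample_id == "s001", ]
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 100)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[n_snp])
  expect_equal(segs$length_mb, (pos[n_snp] - pos[1] + 1) / 1e6)
  ora <- oracle_roh(rep(0L, n_snp), pos, min_snps = 50)
  expect_equal(segs$start_bp, ora$start_bp)
  expect_equal(segs$n_snps, ora$n_snps)
  # insert a 1.2 Mb gap mid-run: the run must split, matching the oracle
  pos2 <- pos; pos2[51:n_snp] <- pos2[51:n_snp] + 1.2e6
  g2 <- make_geno(rbind(calls, other), pos = pos2)
  segs2 <- detect_roh(g2, roh_params(min_snps = 40))
  segs2 <- segs2[segs2$sample_id == "s001", ]
  ora2 <- oracle_roh(rep(0L, n_snp), pos2, min_snps = 40)
  expect_equal(nrow(segs2), nrow(ora2))
  expect_equal(segs2$start_bp, ora2$start_bp)
  expect_equal(segs2$end_bp, ora2$end_bp)
  expect_gt(nrow(segs2), 1)
})

test_that("detected segments respect every stated constraint on a noisy
           simulated sample", {
  withr::local_seed(41)
  cfg <- wf_config(populations = list(list(label = "inb", size = 20,
                                           n_sample = 10)),
                   n_generations = 40, n_chromosomes = 2,
                   chrom_length_bp = 8e6, snps_per_chrom = 150,
                   mating = "small_flock", flock_size = 5, seed = 77)
  g <- simulate_wf(cfg)$genotypes
  params <- roh_params(min_snps = 20, min_length_kb = 500)
  segs <- detect_roh(g, params)
  expect_gt(nrow(segs), 0)
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, ]
    vi <- which(g$variants$chrom == s$chrom &
                g$variants$pos_bp >= s$start_bp &
                g$variants$pos_bp <= s$end_bp)
    calls <- g$calls[g$samples$sample_id == s$sample_id, vi]
    expect_true(all(calls != 1, na.rm = TRUE))          # no heterozygote
    expect_equal(length(vi), s$n_snps)
    expect_gte(s$n_snps, params$min_snps)
    expect_gte(s$end_bp - s$start_bp + 1, params$min_length_kb * 1000)
    gaps <- diff(g$variants$pos_bp[vi])
    expect_true(all(gaps <= params$max_gap_kb * 1000))
    expect_lte(((s$end_bp - s$start_bp + 1) / 1000) / s$n_snps,
               params$density_kb_per_snp)
  }
})

test_that("length classes use half-open intervals and conserve total
           length", {
  segs <- data.frame(sample_id = "x", population = "p", chrom = "1",
                     start_bp = c(1, 1, 1), end_bp = c(3e6, 4.9e6, 5e6),
                     n_snps = 10,
                     length_mb = c(3, 4.9, 5.0))
  cls <- classify_roh(segs)
  expect_equal(cls$mb_1_5, 7.9)      # 3 + 4.9
  expect_equal(cls$mb_5_10, 5.0)     # the 5.0 Mb boundary case moves up
  expect_equal(cls$total_mb, sum(segs$length_mb))
  withr::local_seed(42)
  rnd <- data.frame(sample_id = sample(c("a", "b"), 30, TRUE),
                    length_mb = runif(30, 1, 30))
  cls2 <- classify_roh(rnd)
  expect_equal(cls2$total_mb,
               rowSums(cls2[, c("mb_1_5", "mb_5_10", "mb_10_15",
                                "mb_15_20", "mb_gt20")]))
})

test_that("inbreeding coefficients reproduce their closed forms", {
  # fully homozygous sample whose single ROH tiles the covered chromosome
  n_snp <- 60
  pos <- seq(1e5, by = 1e5, length.out = n_snp)
  calls <- rbind(rep(0L, n_snp), rep(1L, n_snp), rep(2L, n_snp),
                 rep(1L, n_snp))
  g <- make_geno(calls, pos = pos)
  segs <- detect_roh(g, roh_params(min_snps = 10))
  rec <- suppressWarnings(inbreeding_coefficients(g, segs))
  expect_equal(rec$F_ROH[1], 1)
  expect_equal(rec$Ho[1], 0)
  expect_equal(rec$Ho[2], 1)
  # single SNP at p = 0.5: known F_GRM contributions
  g1 <- make_geno(rbind(1L, 1L, 0L, 2L))   # freqs: p = 0.5
  rec1 <- suppressWarnings(
    inbreeding_coefficients(g1, detect_roh(g1, roh_params(min_snps = 2))))
  expect_equal(rec1$F_GRM[1], -1)          # het: (1-1)^2/0.5 - 1
  expect_equal(rec1$F_GRM[4], 1)           # hom-alt: (2-1)^2/0.5 - 1
})

test_that("F_HOM and F_IS follow their defining ratios", {
  # O_hom = 900, E_hom = 800, m = 1000 -> F_HOM = 0.5
  expect_equal((900 - 800) / (1000 - 800), 0.5)
  # construct genotypes with known observed/expected heterozygosity:
  # every SNP at p = 0.5, 4 samples with 1 het each at every SNP
  calls <- matrix(c(1L, 0L, 2L, 1L), 4, 40)
  g <- make_geno(calls)
  rec <- inbreeding_coefficients(g, detect_roh(g, roh_params(min_snps = 5)))
  # Ho_j = 0.5 at every SNP, He_j = 2*0.5*0.5 = 0.5 -> F_IS = 0
  expect_equal(rec$F_IS, rep(0, 4))
  # F_HOM per sample: het sample O_hom = 0, E_hom = 0.5 * m
  m <- 40
  expect_equal(rec$F_HOM[1], (0 - m / 2) / (m - m / 2))
  expect_equal(rec$F_HOM[2], (m - m / 2) / (m - m / 2))
})

test_that("F_ROH grows as segments are appended and is zero without any", {
  n_snp <- 80
  g <- make_geno(matrix(0L, 1, n_snp))
  none <- detect_roh(g, roh_params(min_snps = 200))   # threshold too high
  expect_equal(nrow(none), 0)
  rec0 <- suppressWarnings(inbreeding_coefficients(g, none))
  expect_equal(rec0$F_ROH, 0)
  seg1 <- data.frame(sample_id = "s001", population = "p1", chrom = "1",
                     start_bp = 1e5, end_bp = 2e6, n_snps = 20,
                     length_mb = 1.9001)
  seg2 <- rbind(seg1, data.frame(sample_id = "s001", population = "p1",
                                 chrom = "1", start_bp = 5e6, end_bp = 7e6,
                                 n_snps = 21, length_mb = 2.0001))
  f1 <- suppressWarnings(inbreeding_coefficients(g, seg1))$F_ROH
  f2 <- suppressWarnings(inbreeding_coefficients(g, seg2))$F_ROH
  expect_gt(f2, f1)
  expect_gt(f1, 0)
})

test_that("small-flock mating elevates F_ROH above random mating, and
           random-mating F_GRM centres near zero", {
  withr::local_seed(51)
  run <- function(mat) {
    cfg <- wf_config(populations = list(list(label = "p", size = 40,
                                             n_sample = 20)),
                     n_generations = 30, n_chromosomes = 2,
                     chrom_length_bp = 8e6, snps_per_chrom = 160,
                     mating = mat, flock_size = 8, seed = 99)
    g <- simulate_wf(cfg)$genotypes
    segs <- detect_roh(g, roh_params(min_snps = 15, min_length_kb = 500))
    mean(suppressWarnings(inbreeding_coefficients(g, segs))$F_ROH)
  }
  expect_gt(run("small_flock"), run("random"))
  # large random-mating population in Hardy-Weinberg proportions
  withr::local_seed(52)
  p <- runif(10000, 0.05, 0.95)
  calls <- t(replicate(100, rbinom(10000, 2, p)))
  grec <- suppressWarnings(
    inbreeding_coefficients(make_geno(calls),
                            data.frame(sample_id = character(),
                                       population = character(),
                                       chrom = character(),
                                       start_bp = numeric(),
                                       end_bp = numeric(),
                                       n_snps = integer(),
                                       length_mb = numeric())))
  expect_lt(abs(mean(grec$F_GRM)), 0.02)
})
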