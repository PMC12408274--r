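test_that("EHH is one among identical carriers and follows the group-split
           closed form", {
  H <- matrix(0L, 20, 30)
  H[1:10, 15] <- 1L                      # derived carriers all identical
  h <- make_haps(H)
  e <- ehh_decay(h, 15, "derived")
  expect_true(all(e$ehh == 1))
  # carriers split into two equal groups immediately next to the focal site
  H2 <- H
  H2[1:5, 16] <- 1L                      # half the carriers diverge
  e2 <- ehh_decay(make_haps(H2), 15, "derived")
  right1 <- e2$ehh[e2$distance_bp > 0][1]
  expect_equal(right1, 2 * choose(5, 2) / choose(10, 2))
  expect_error(ehh_decay(make_haps(matrix(0L, 6, 10)), 5, "derived"),
               "singleton|fewer than 2")
})

test_that("EHH is non-increasing outward and matches the brute-force
           pairwise oracle at every site", {
  withr::local_seed(71)
  H <- matrix(rbinom(20 * 40, 1, 0.5), 20, 40)
  H[, 20] <- rep(c(0L, 1L), each = 10)
  h <- make_haps(H)
  for (al in c("ancestral", "derived")) {
    e <- ehh_decay(h, 20, al, cutoff = 0)    # no truncation: full curve
    left <- e$ehh[e$distance_bp <= 0]
    right <- e$ehh[e$distance_bp >= 0]
    expect_true(all(diff(left) >= -1e-12))
    expect_true(all(diff(right) <= 1e-12))
    av <- if (al == "derived") 1L else 0L
    for (k in seq_len(nrow(e))) {
      target <- which(h$positions_bp == e$position_bp[k])
      expect_equal(e$ehh[k], oracle_ehh(H, 20, av, target),
                   tolerance = 1e-12)
    }
  }
})

test_that("iHS is zero under mirror-symmetric haplotype structure and
           standardization centres every frequency bin", {
  # derived and ancestral carriers carry identical haplotype patterns
  pat <- matrix(rbinom(10 * 41, 1, 0.5), 10, 41)
  H <- rbind(pat, pat)
  H[1:10, 21] <- 0L; H[11:20, 21] <- 1L
  h <- make_haps(H)
  raw <- ihs_scan(h, maf_min = 0.3, cutoff = 0)
  focal <- raw[raw$pos_bp == h$positions_bp[21], ]
  expect_equal(focal$raw_ihs, 0, tolerance = 1e-12)

  withr::local_seed(72)
  hs <- lapply(1:2, function(ch) {
    HH <- matrix(rbinom(40 * 120, 1, runif(120, 0.1, 0.9)), 40, 120,
                 byrow = FALSE)
    haplotype_set(as.character(ch), seq(5e4, by = 5e4, length.out = 120),
                  HH, sprintf("s%02d", 1:20))
  })
  res <- ihs_scan(hs, cutoff = 0.25)
  scored <- res[!is.na(res$std_ihs), ]
  expect_gt(nrow(scored), 20)
  bin <- floor(scored$derived_freq / 0.05)
  for (s in unique(paste(scored$chrom, bin))) {
    k <- paste(scored$chrom, bin) == s
    if (sum(k) >= 2) {
      expect_lt(abs(mean(scored$std_ihs[k])), 1e-9)
      expect_lt(abs(sd(scored$std_ihs[k]) - 1), 1e-9)
    }
  }
})

test_that("H12 reproduces its closed forms and the string-counting oracle", {
  # all gametes identical
  expect_equal(h12_scan(make_haps(matrix(1L, 12, 25)))$value, 1)
  # two haplotypes at 0.5/0.5 pool to H12 = 1
  H <- rbind(matrix(0L, 6, 25), matrix(1L, 6, 25))
  expect_equal(h12_scan(make_haps(H))$value, 1)
  # frequencies (0.4, 0.3, 0.2, 0.1): 0.7^2 + 0.2^2 + 0.1^2 = 0.54
  base <- matrix(0L, 20, 25)
  base[9:14, 1] <- 1L                                   # 0.3 group
  base[15:18, 2] <- 1L                                  # 0.2 group
  base[19:20, 3] <- 1L                                  # 0.1 group
  expect_equal(h12_scan(make_haps(base))$value, 0.54)
  withr::local_seed(73)
  Hr <- matrix(rbinom(30 * 60, 1, 0.5), 30, 60)
  hr <- make_haps(rbind(Hr, Hr[1:10, ]))                # 40 gametes
  scan <- h12_scan(hr, window_snps = 25, step_snps = 1)
  for (k in seq_len(nrow(scan))) {
    cols <- which(hr$positions_bp >= scan$start_bp[k] &
                  hr$positions_bp <= scan$end_bp[k])
    expect_equal(scan$value[k], oracle_h12(hr$haplotypes[, cols]),
                 tolerance = 1e-12)
  }
  expect_true(all(scan$value > 0 & scan$value <= 1))
})

test_that("pooled heterozygosity follows its count form and degenerates
           loudly", {
  # sum(n_MAJ) = 80, sum(n_MIN) = 20 -> Hp = 0.32 ; fixed sites -> Hp = 0
  expect_equal(2 * 80 * 20 / (80 + 20)^2, 0.32)
  withr::local_seed(74)
  n <- 10
  calls <- cbind(matrix(rbinom(n * 20, 2, 0.3), n, 20),
                 matrix(0L, n, 22))                   # tail region fixed
  g <- make_geno(calls, pos = c(seq(1e4, by = 1e4, length.out = 20),
                                seq(2.1e5, by = 1e4, length.out = 22)))
  res <- zhp_scan(g, window_bp = 2e5, min_snps = 5)
  fixed_win <- res[res$start_bp >= 2e5 + 1, ]
  expect_gt(nrow(fixed_win), 0)
  expect_true(all(fixed_win$hp == 0))
  expect_equal(res$value[which.min(res$hp)], min(res$value))
  counted <- res[res$start_bp == 1, ]
  smaj <- sum(pmax(colSums(calls[, 1:20]), 2 * n - colSums(calls[, 1:20])))
  smin <- sum(pmin(colSums(calls[, 1:20]), 2 * n - colSums(calls[, 1:20])))
  expect_equal(counted$hp, 2 * smaj * smin / (smaj + smin)^2)
  # every window identical -> sd = 0 -> explicit error
  g2 <- make_geno(matrix(rep(c(0L, 2L), each = 5), 10, 40),
                  pos = seq(1e4, by = 1e4, length.out = 40))
  expect_error(zhp_scan(g2, window_bp = 1e5, min_snps = 2), "ZHp undefined")
})

test_that("windowed diversity and Tajima's D match first-principles
           oracles", {
  # monomorphic window: pi = 0, D missing
  gmono <- make_geno(matrix(0L, 6, 15), pos = seq(1e4, by = 1e4,
                                                  length.out = 15))
  res <- window_frequency_stats(gmono, window_bp = 3e5, min_snps = 10)
  expect_equal(res$pi, 0)
  expect_true(is.na(res$tajima_d))
  # N = 10 haplotypes, 5 singleton sites in one whole-window block
  H <- matrix(0L, 10, 12)
  for (j in 1:5) H[j, j] <- 1L
  hs <- make_haps(H, pos = seq(1e4, by = 1e4, length.out = 12))
  res2 <- window_frequency_stats(list(hs), window_bp = 3e5, min_snps = 10)
  expect_equal(res2$tajima_d, oracle_tajima_d(H), tolerance = 1e-12)
  expect_equal(res2$tajima_d, -1.741, tolerance = 1e-3)
  expect_equal(res2$pi * 3e5, oracle_pairwise_pi(H), tolerance = 1e-12)
  # random haplotype fixture: window pi equals the pairwise-difference count
  withr::local_seed(75)
  Hr <- matrix(rbinom(16 * 30, 1, 0.4), 16, 30)
  hr <- make_haps(Hr, pos = seq(5e3, by = 9e3, length.out = 30))
  res3 <- window_frequency_stats(list(hr), window_bp = 3e5, min_snps = 10)
  expect_equal(res3$pi * 3e5, oracle_pairwise_pi(Hr), tolerance = 1e-10)
  expect_equal(res3$tajima_d, oracle_tajima_d(Hr), tolerance = 1e-10)
  expect_gte(res3$pi, 0)
})

test_that("standardized iHS tails on a neutral panel are near the Gaussian
           reference", {
  withr::local_seed(76)
  cfg <- wf_config(populations = list(list(label = "n", size = 150,
                                           n_sample = 20)),
                   n_generations = 60, n_chromosomes = 3,
                   chrom_length_bp = 10e6, snps_per_chrom = 300,
                   cm_per_mb = 8, seed = 176)
  s <- simulate_wf(cfg)
  hp <- lapply(s$haplotypes, function(x) polarize_to_major(x)$haplotypes)
  res <- ihs_scan(hp)
  z <- res$std_ihs[!is.na(res$std_ihs)]
  expect_gt(length(z), 200)
  frac <- mean(abs(z) > 2)
  expect_gt(frac, 0.046 - 0.02)
  expect_lt(frac, 0.046 + 0.02)
})
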