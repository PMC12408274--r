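# Independent brute-force implementations used as oracles. Each one follows
# the textbook definition by a different algebraic/algorithmic route than the
# package code so agreement is meaningful.

# Weir & Cockerham (1984) two-population theta via the allele-indicator
# ANOVA route: mean squares among populations (MSP) and within (MSG/MSI)
# computed from per-individual allele dosages.
oracle_wc_fst <- function(callsA, callsB) {
  per_snp_a <- numeric(ncol(callsA))
  per_snp_d <- numeric(ncol(callsA))
  theta <- rep(NA_real_, ncol(callsA))
  for (j in seq_len(ncol(callsA))) {
    xa <- callsA[, j]; xb <- callsB[, j]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    n1 <- length(xa); n2 <- length(xb)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(xa) / 2; p2 <- mean(xb) / 2
    if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) next
    h1 <- mean(xa == 1); h2 <- mean(xb == 1)
    nbar <- (n1 + n2) / 2
    CV <- ((n1 - nbar)^2 + (n2 - nbar)^2) / 2   # variance of sizes
    nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
    nc <- nc / 1                                 # r - 1 = 1
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
           (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
           (pbar * (1 - pbar) - s2 / 2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    if (a + b + cc == 0) next
    per_snp_a[j] <- a
    per_snp_d[j] <- a + b + cc
    theta[j] <- a / (a + b + cc)
  }
  list(theta = theta,
       mean = sum(per_snp_a) / sum(per_snp_d))
}

# EHH by exhaustive pairwise comparison of carrier gametes
oracle_ehh <- function(H, focal, allele_val, target) {
  carriers <- which(H[, focal] == allele_val)
  n <- length(carriers)
  span <- min(focal, target):max(focal, target)
  same <- 0
  for (a in seq_len(n - 1))
    for (b in (a + 1):n)
      if (all(H[carriers[a], span] == H[carriers[b], span])) same <- same + 1
  same / choose(n, 2)
}

# H12 by direct string counting
oracle_h12 <- function(H) {
  strs <- apply(H, 1, paste, collapse = "/")
  p <- sort(as.vector(table(strs)) / nrow(H), decreasing = TRUE)
  if (length(p) == 1) return(1)
  (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
}

# nucleotide diversity by exhaustive pairwise difference counting
oracle_pairwise_pi <- function(H) {
  n <- nrow(H); tot <- 0
  for (a in seq_len(n - 1))
    for (b in (a + 1):n)
      tot <- tot + sum(H[a, ] != H[b, ])
  tot / choose(n, 2)
}

# Tajima's D from first principles for complete data
oracle_tajima_d <- function(H) {
  n <- nrow(H)
  freq <- colMeans(H)
  S <- sum(freq > 0 & freq < 1)
  if (S == 0) return(NA_real_)
  pi_sum <- oracle_pairwise_pi(H)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Benjamini-Hochberg step-up by the literal procedure
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# straightforward ROH scanner: recomputes window hits and SNP eligibility
# with naive loops, then walks runs directly
oracle_roh <- function(calls, pos, min_snps, min_length_kb = 1000,
                       max_gap_kb = 1000, density_kb_per_snp = 150,
                       scan_w = 50, hit_thr = 0.05, max_het = 0,
                       max_miss = 1) {
  m <- length(calls)
  W <- min(scan_w, m)
  n_win <- m - W + 1
  hits <- logical(n_win)
  for (w in seq_len(n_win)) {
    seg <- calls[w:(w + W - 1)]
    hits[w] <- sum(seg == 1, na.rm = TRUE) <= max_het &&
               sum(is.na(seg)) <= max_miss
  }
  elig <- logical(m)
  for (j in seq_len(m)) {
    wins <- max(1, j - W + 1):min(j, n_win)
    elig[j] <- mean(hits[wins]) >= hit_thr
  }
  ok <- elig & !(calls == 1 & !is.na(calls))
  segs <- NULL
  i <- 1
  while (i <= m) {
    if (!ok[i]) { i <- i + 1; next }
    j <- i
    while (j < m && ok[j + 1] && (pos[j + 1] - pos[j]) <= max_gap_kb * 1000)
      j <- j + 1
    len_bp <- pos[j] - pos[i] + 1
    if (j - i + 1 >= min_snps && len_bp >= min_length_kb * 1000 &&
        (len_bp / 1000) / (j - i + 1) <= density_kb_per_snp)
      segs <- rbind(segs, data.frame(start_bp = pos[i], end_bp = pos[j],
                                     n_snps = j - i + 1))
    i <- j + 1
  }
  segs
}

# greedy all-pairs LD pruner over one window ordering (mirrors the
# documented tie-break: worst pair first, drop lower-MAF, then later SNP)
oracle_prune <- function(calls, mafs, r2_thr) {
  keep <- seq_len(ncol(calls))
  repeat {
    worst <- NULL; worst_r2 <- r2_thr
    if (length(keep) >= 2) {
      for (a in seq_len(length(keep) - 1)) {
        for (b in (a + 1):length(keep)) {
          x <- calls[, keep[a]]; y <- calls[, keep[b]]
          ok <- !is.na(x) & !is.na(y)
          if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
          r2 <- cor(x[ok], y[ok])^2
          if (r2 > worst_r2) { worst_r2 <- r2; worst <- c(keep[a], keep[b]) }
        }
      }
    }
    if (is.null(worst)) break
    drop <- if (mafs[worst[1]] < mafs[worst[2]]) worst[1]
            else if (mafs[worst[2]] < mafs[worst[1]]) worst[2] else worst[2]
    keep <- setdiff(keep, drop)
  }
  keep
}

# small builders -------------------------------------------------------------

make_geno <- function(calls, chrom = "1", pos = NULL, pops = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(pos)) pos <- seq(1e5, by = 1e5, length.out = m)
  if (is.null(pops)) pops <- rep("p1", n)
  if (length(chrom) == 1) chrom <- rep(chrom, m)
  genotype_matrix(calls,
    data.frame(sample_id = sprintf("s%03d", seq_len(n)), population = pops,
               stringsAsFactors = FALSE),
    data.frame(chrom = chrom, pos_bp = pos,
               id = sprintf("v%04d", seq_len(m)), a1 = "A", a2 = "B",
               stringsAsFactors = FALSE))
}

make_haps <- function(H, chrom = "1", pos = NULL) {
  H <- as.matrix(H)
  if (is.null(pos)) pos <- seq(1e4, by = 1e4, length.out = ncol(H))
  haplotype_set(chrom, pos, H, sprintf("s%03d", seq_len(nrow(H) / 2)))
}
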