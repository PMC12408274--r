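#' Extended haplotype homozygosity decay around a focal allele
#'
#' For the gametes carrying the chosen allele at the focal site, EHH at a
#' site `x` is the probability that two randomly drawn carrier gametes are
#' identical over every SNP between the focal site and `x`:
#' `EHH(x) = sum_k C(n_k, 2) / C(n_core, 2)` over the haplotype groups
#' formed by the intervening SNPs. EHH is 1 at the focal site and
#' non-increasing outward; the decay curve is truncated one site after EHH
#' first drops below `cutoff` in each direction.
#'
#' @param h a `haplotype_set`
#' @param focal_index column index of the focal site
#' @param allele `"ancestral"` (allele 0) or `"derived"` (allele 1)
#' @param cutoff truncation threshold (default 0.05)
#' @return data.frame `position_bp`, `distance_bp` (signed), `ehh`, sorted
#'   by position and including the focal site. Attribute `complete_left` /
#'   `complete_right` record whether EHH reached the cutoff before the
#'   chromosome end.
#' @export
ehh_decay <- function(h, focal_index, allele = c("derived", "ancestral"),
                      cutoff = 0.05) {
  allele <- match.arg(allele)
  aval <- if (allele == "derived") 1L else 0L
  carriers <- which(h$haplotypes[, focal_index] == aval)
  if (length(carriers) < 2)
    stop("focal allele carried by fewer than 2 gametes (singleton)")
  left <- ehh_one_side(h, focal_index, carriers, -1L, cutoff)
  right <- ehh_one_side(h, focal_index, carriers, +1L, cutoff)
  pos <- h$positions_bp
  df <- data.frame(
    position_bp = c(rev(pos[left$sites]), pos[focal_index], pos[right$sites]),
    ehh = c(rev(left$ehh), 1, right$ehh))
  df$distance_bp <- df$position_bp - pos[focal_index]
  attr(df, "complete_left") <- left$complete
  attr(df, "complete_right") <- right$complete
  df[, c("position_bp", "distance_bp", "ehh")]
}

# walk outward from the focal site refining carrier haplotype groups
ehh_one_side <- function(h, focal_index, carriers, dir, cutoff) {
  n_core <- length(carriers)
  denom <- choose(n_core, 2)
  groups <- list(carriers)
  sites <- integer(); ehh <- numeric(); complete <- FALSE
  j <- focal_index + dir
  n_sites <- ncol(h$haplotypes)
  while (j >= 1 && j <= n_sites) {
    groups <- unlist(lapply(groups, function(gi) {
      al <- h$haplotypes[gi, j]
      sp <- split(gi, al)
      sp[lengths(sp) > 0]
    }), recursive = FALSE)
    e <- sum(vapply(groups, function(gi) choose(length(gi), 2), 0)) / denom
    sites <- c(sites, j); ehh <- c(ehh, e)
    if (e < cutoff) { complete <- TRUE; break }
    j <- j + dir
  }
  list(sites = sites, ehh = ehh, complete = complete)
}

# trapezoid integral of the one-sided EHH curve (focal EHH = 1 at distance 0)
ihh_one_side <- function(pos, focal_index, side) {
  d <- abs(side$dist); e <- side$ehh
  d <- c(0, d); e <- c(1, e)
  if (length(d) < 2) return(0)
  sum(diff(d) * (utils::head(e, -1) + utils::tail(e, -1)) / 2)
}

#' Integrated haplotype score scan
#'
#' Computes the unstandardized `iHS = ln(iHH_A / iHH_D)` at every site with
#' minor allele frequency at least `maf_min`, where `iHH` is the trapezoid
#' integral of the EHH decay curve over physical distance for the
#' ancestral (A) and derived (D) alleles, each truncated where EHH drops
#' below `cutoff`. Sites where either allele's EHH never reaches the cutoff
#' before a chromosome end, or where either allele is a singleton, are
#' reported with missing scores. Raw scores are then z-standardized within
#' derived-allele-frequency bins of width `freq_bin`, separately per
#' chromosome (or jointly, with `standardize_per = "genome"`); bins with
#' fewer than 2 scored sites are left unstandardized.
#'
#' Ancestral state is unknowable from array data, so allele 0 of the
#' haplotype coding is treated as ancestral; build haplotype sets with
#' allele 0 = dataset major allele for the conventional polarization.
#'
#' @param hsets a `haplotype_set` or list of them (one per chromosome)
#' @param maf_min minimum minor allele frequency (default 0.05)
#' @param freq_bin derived-frequency bin width for standardization
#' @param standardize_per `"chromosome"` (default) or `"genome"`
#' @param cutoff EHH truncation threshold
#' @return data.frame: `chrom`, `pos_bp`, `derived_freq`, `raw_ihs`,
#'   `std_ihs`
#' @export
ihs_scan <- function(hsets, maf_min = 0.05, freq_bin = 0.05,
                     standardize_per = c("chromosome", "genome"),
                     cutoff = 0.05) {
  standardize_per <- match.arg(standardize_per)
  if (inherits(hsets, "haplotype_set")) hsets <- list(hsets)
  per_chrom <- lapply(hsets, function(h) {
    n_g <- nrow(h$haplotypes)
    daf <- colMeans(h$haplotypes)
    keep <- pmin(daf, 1 - daf) >= maf_min
    raw <- rep(NA_real_, ncol(h$haplotypes))
    for (j in which(keep)) {
      anc <- which(h$haplotypes[, j] == 0L)
      der <- which(h$haplotypes[, j] == 1L)
      if (length(anc) < 2 || length(der) < 2) next
      sa <- ehh_two_sides(h, j, anc, cutoff)
      sd_ <- ehh_two_sides(h, j, der, cutoff)
      if (!sa$complete || !sd_$complete) next
      if (sa$ihh <= 0 || sd_$ihh <= 0) next
      raw[j] <- log(sa$ihh / sd_$ihh)
    }
    data.frame(chrom = h$chrom, pos_bp = h$positions_bp,
               derived_freq = daf, raw_ihs = raw,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  })
  res <- do.call(rbind, per_chrom)
  if (!nrow(res)) { res$std_ihs <- numeric(); return(res) }
  res$std_ihs <- NA_real_
  bin <- pmin(floor(res$derived_freq / freq_bin), 1 / freq_bin - 1)
  strat <- if (standardize_per == "chromosome")
    paste(res$chrom, bin) else as.character(bin)
  for (s in unique(strat)) {
    k <- which(strat == s & !is.na(res$raw_ihs))
    if (length(k) < 2) next
    mu <- mean(res$raw_ihs[k]); sg <- stats::sd(res$raw_ihs[k])
    if (sg > 0) res$std_ihs[k] <- (res$raw_ihs[k] - mu) / sg
  }
  rownames(res) <- NULL
  res
}

ehh_two_sides <- function(h, j, carriers, cutoff) {
  l <- ehh_one_side(h, j, carriers, -1L, cutoff)
  r <- ehh_one_side(h, j, carriers, +1L, cutoff)
  pos <- h$positions_bp
  ihh <- ihh_one_side(pos, j, list(dist = pos[j] - pos[l$sites], ehh = l$ehh)) +
         ihh_one_side(pos, j, list(dist = pos[r$sites] - pos[j], ehh = r$ehh))
  # a side that hits the chromosome boundary without decaying is incomplete,
  # unless the chromosome end IS the focal site's side (no sites there at
  # all); a non-positive cutoff means integrate-to-end deliberately
  complete <- cutoff <= 0 ||
    ((l$complete || j == 1L) && (r$complete || j == ncol(h$haplotypes)))
  list(ihh = ihh, complete = complete)
}

#' Haplotype homozygosity H12 scan
#'
#' Within each window of `window_snps` consecutive SNPs (advanced by
#' `step_snps`), gametes are grouped by their exact haplotype string and
#' sorted by frequency `p1 >= p2 >= ...`; `H12 = (p1 + p2)^2 +
#' sum_{i>=3} p_i^2`, which pools the two most frequent haplotypes to gain
#' power on soft sweeps.
#'
#' @param hsets a `haplotype_set` or list of them
#' @param window_snps SNPs per window (default 25)
#' @param step_snps step between windows (default 1)
#' @return data.frame: `chrom`, `start_bp`, `end_bp`, `statistic`
#'   (`"H12"`), `value`, `n_snps`
#' @export
h12_scan <- function(hsets, window_snps = 25L, step_snps = 1L) {
  if (inherits(hsets, "haplotype_set")) hsets <- list(hsets)
  out <- lapply(hsets, function(h) {
    m <- ncol(h$haplotypes)
    if (m < window_snps)
      return(NULL)
    starts <- seq(1L, m - window_snps + 1L, by = step_snps)
    # windows of <= 30 SNPs fit in a double-precision integer hash
    # (2^window_snps < 2^53), so gametes can be grouped numerically
    # instead of by string concatenation
    wts <- 2^(seq_len(window_snps) - 1)
    vals <- vapply(starts, function(s) {
      cols <- s:(s + window_snps - 1L)
      key <- if (window_snps <= 50)
        as.vector(h$haplotypes[, cols, drop = FALSE] %*% wts)
      else apply(h$haplotypes[, cols, drop = FALSE], 1, paste, collapse = "")
      p <- sort(table(key) / length(key), decreasing = TRUE)
      if (length(p) == 1) 1 else (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
    }, 0)
    data.frame(chrom = h$chrom, start_bp = h$positions_bp[starts],
               end_bp = h$positions_bp[starts + window_snps - 1L],
               statistic = "H12", value = vals, n_snps = window_snps,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), statistic = character(),
                      value = numeric(), n_snps = integer())
  rownames(res) <- NULL
  res
}

#' Pooled-heterozygosity ZHp scan
#'
#' In sliding windows of `window_bp` (50\% overlap by default), major and
#' minor allele counts are summed over the window's SNPs and the pooled
#' heterozygosity computed as
#' `Hp = 2 * sum(n_MAJ) * sum(n_MIN) / (sum(n_MAJ) + sum(n_MIN))^2`;
#' `ZHp` standardizes Hp to zero mean and unit variance over all retained
#' windows genome-wide. Strongly negative ZHp marks swept regions.
#' Incomplete terminal windows are never emitted - few-SNP slivers at
#' chromosome ends carry extreme-variance statistics - but a chromosome
#' shorter than one window is scanned as a single whole window.
#'
#' @param g a `genotype_matrix` (one population)
#' @param window_bp window size (default 200 kb)
#' @param overlap fractional window overlap (default 0.5)
#' @param min_snps minimum SNPs per retained window (default 10)
#' @return data.frame: `chrom`, `start_bp`, `end_bp`, `statistic`
#'   (`"ZHp"`), `value`, `hp`, `n_snps`
#' @export
zhp_scan <- function(g, window_bp = 200000, overlap = 0.5, min_snps = 10L) {
  step <- window_bp * (1 - overlap)
  n2 <- colSums(g$calls, na.rm = TRUE)                  # a2 copies
  ntot <- 2 * colSums(!is.na(g$calls))
  n_major <- pmax(n2, ntot - n2); n_minor <- pmin(n2, ntot - n2)
  rows <- list()
  for (ch in unique(g$variants$chrom)) {
    vi <- which(g$variants$chrom == ch)
    pos <- g$variants$pos_bp[vi]
    # incomplete terminal windows are never emitted (few-SNP slivers carry
    # extreme-variance statistics); a chromosome shorter than one window
    # is scanned as a single whole-chromosome window
    starts <- if (max(pos) < window_bp) 1
              else seq(1, max(pos) - window_bp + 1, by = step)
    for (s in starts) {
      k <- vi[pos >= s & pos < s + window_bp]
      if (length(k) < min_snps) next
      smaj <- sum(n_major[k]); smin <- sum(n_minor[k])
      hp <- 2 * smaj * smin / (smaj + smin)^2
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start_bp = s, end_bp = s + window_bp - 1,
        hp = hp, n_snps = length(k), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no windows with at least ", min_snps, " SNPs")
  res <- do.call(rbind, rows)
  sg <- stats::sd(res$hp)
  if (sg == 0)
    stop("pooled heterozygosity identical in every window; ZHp undefined")
  res$statistic <- "ZHp"
  res$value <- (res$hp - mean(res$hp)) / sg
  res[, c("chrom", "start_bp", "end_bp", "statistic", "value", "hp",
          "n_snps")]
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed nucleotide diversity and Tajima's D
#'
#' In non-overlapping windows of `window_bp`, computes per-bp nucleotide
#' diversity and Tajima's D from allele counts, so the same code serves
#' unphased genotypes or phased haplotypes. Per site with `N` non-missing
#' allele copies and `j` alternate copies, the unbiased heterozygosity is
#' `pi_j = 2 j (N - j) / (N (N - 1))`; window `pi` is `sum(pi_j) /
#' window_bp`. Tajima's D uses the segregating-site count `S`, the pairwise
#' sum `sum(pi_j)` and the standard sample-size constants at `N` = the
#' (rounded) mean allele-copy count of the window's sites. Windows with
#' fewer than `min_snps` SNPs are dropped; windows with `S = 0` report
#' `pi = 0` and missing D. As for [zhp_scan()], incomplete terminal
#' windows are not emitted, except that a chromosome shorter than one
#' window forms a single whole window.
#'
#' @param g a `genotype_matrix` (one population) or a list of
#'   `haplotype_set`
#' @param window_bp window size (default 300 kb)
#' @param min_snps minimum SNPs per retained window (default 10)
#' @param min_copies minimum non-missing allele copies for a site to be
#'   used (default 4)
#' @return data.frame: `chrom`, `start_bp`, `end_bp`, `pi`, `tajima_d`,
#'   `n_snps`
#' @export
window_frequency_stats <- function(g, window_bp = 300000, min_snps = 10L,
                                   min_copies = 4L) {
  if (inherits(g, "haplotype_set") ||
      (is.list(g) && !inherits(g, "genotype_matrix") &&
       inherits(g[[1]], "haplotype_set")))
    g <- haplotypes_to_genotypes(g)
  j_alt <- colSums(g$calls, na.rm = TRUE)
  N <- 2 * colSums(!is.na(g$calls))
  usable <- N >= min_copies
  pi_site <- ifelse(usable, 2 * j_alt * (N - j_alt) / (N * pmax(N - 1, 1)), NA)
  seg <- usable & j_alt > 0 & j_alt < N
  rows <- list()
  for (ch in unique(g$variants$chrom)) {
    vi <- which(g$variants$chrom == ch)
    pos <- g$variants$pos_bp[vi]
    # complete windows only; short chromosomes get one whole window
    starts <- if (max(pos) < window_bp) 1
              else seq(1, max(pos) - window_bp + 1, by = window_bp)
    for (s in starts) {
      k <- vi[pos >= s & pos < s + window_bp]
      k <- k[usable[k]]
      if (length(k) < min_snps) next
      S <- sum(seg[k])
      pi_sum <- sum(pi_site[k])
      D <- NA_real_
      if (S > 0) {
        nmean <- max(round(mean(N[k])), 4)
        ct <- tajima_constants(nmean)
        vr <- ct$e1 * S + ct$e2 * S * (S - 1)
        if (vr > 0) D <- (pi_sum - S / ct$a1) / sqrt(vr)
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start_bp = s, end_bp = s + window_bp - 1,
        pi = pi_sum / window_bp, tajima_d = D, n_snps = length(k),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), pi = numeric(),
                      tajima_d = numeric(), n_snps = integer()))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
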