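#' Minimum SNP count for ROH calling (L parameter)
#'
#' Computes the minimum number of SNPs a run of homozygosity must contain so
#' that the expected number of chance runs across the whole panel stays
#' below `alpha`:
#' `L = ceiling( log(alpha / (n_snps * n_individuals)) / log(1 - mean_het) )`,
#' clamped below at 2.
#'
#' @param n_snps number of SNPs in the panel
#' @param n_individuals number of genotyped individuals
#' @param alpha tolerated false-positive rate (default 0.05)
#' @param mean_het mean per-SNP heterozygosity, strictly inside (0, 1)
#' @return integer minimum SNP count
#' @export
l_parameter <- function(n_snps, n_individuals, alpha = 0.05, mean_het) {
  stopifnot(n_snps >= 1, n_individuals >= 1, alpha > 0)
  if (!is.finite(mean_het) || mean_het <= 0 || mean_het >= 1)
    stop("mean_het must lie strictly between 0 and 1")
  ratio <- alpha / (n_snps * n_individuals)
  L <- if (ratio >= 1) 2L else as.integer(ceiling(log(ratio) / log(1 - mean_het)))
  max(L, 2L)
}

#' ROH scanning parameters
#'
#' Bundles the PLINK-style ROH detection thresholds. Defaults follow the
#' small-ruminant settings: minimum run length 1,000 kb, maximum gap
#' 1,000 kb, no heterozygote and at most one missing call per scanning
#' window, density at least one SNP per 150 kb, 50-SNP scanning windows and
#' a 5\% window hit threshold.
#'
#' @param min_length_kb minimum run length (kb)
#' @param max_gap_kb maximum gap between consecutive run SNPs (kb)
#' @param max_het_in_window heterozygous calls tolerated per scanning window
#' @param max_missing_in_window missing calls tolerated per scanning window
#' @param density_kb_per_snp maximum kb per SNP within a run
#' @param min_snps minimum SNPs per run (use [l_parameter()])
#' @param scan_window_snps scanning window size in SNPs
#' @param window_hit_threshold minimum fraction of windows containing a SNP
#'   that must be homozygous-compatible for the SNP to be run-eligible
#' @return list of class `roh_params`
#' @export
roh_params <- function(min_length_kb = 1000, max_gap_kb = 1000,
                       max_het_in_window = 0, max_missing_in_window = 1,
                       density_kb_per_snp = 150, min_snps = 2L,
                       scan_window_snps = 50L, window_hit_threshold = 0.05) {
  stopifnot(min_length_kb > 0, max_gap_kb > 0, density_kb_per_snp > 0,
            min_snps >= 2, scan_window_snps >= 1,
            window_hit_threshold > 0, max_het_in_window >= 0,
            max_missing_in_window >= 0)
  structure(list(min_length_kb = min_length_kb, max_gap_kb = max_gap_kb,
                 max_het_in_window = max_het_in_window,
                 max_missing_in_window = max_missing_in_window,
                 density_kb_per_snp = density_kb_per_snp,
                 min_snps = as.integer(min_snps),
                 scan_window_snps = as.integer(scan_window_snps),
                 window_hit_threshold = window_hit_threshold),
            class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' Reconstruction of the PLINK `--homozyg` scanning algorithm. Per sample
#' and chromosome, a window of `scan_window_snps` SNPs slides one SNP at a
#' time (chromosomes shorter than the window are scanned with a single
#' truncated window). A window is a *hit* when it contains at most
#' `max_het_in_window` heterozygous and at most `max_missing_in_window`
#' missing calls. A SNP is run-eligible when the fraction of windows
#' containing it that are hits is at least `window_hit_threshold`. Candidate
#' runs are maximal stretches of consecutive eligible SNPs with no
#' heterozygous call (missing allowed), split wherever the gap between
#' consecutive SNPs exceeds `max_gap_kb`; a candidate is reported when it
#' has at least `min_snps` SNPs, spans at least `min_length_kb` and its
#' kb-per-SNP density does not exceed `density_kb_per_snp`.
#'
#' @param g a QC'd autosomal `genotype_matrix`
#' @param params a [roh_params()] object
#' @return data.frame of segments: `sample_id`, `population`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_mb`
#' @export
detect_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  out <- vector("list", 0)
  for (ch in unique(g$variants$chrom)) {
    vi <- which(g$variants$chrom == ch)
    pos <- g$variants$pos_bp[vi]
    W <- min(params$scan_window_snps, length(vi))
    n_win <- length(vi) - W + 1L
    for (si in seq_len(n_samples(g))) {
      calls <- g$calls[si, vi]
      het <- !is.na(calls) & calls == 1L
      mis <- is.na(calls)
      # windowed counts via cumulative sums
      cs_het <- cumsum(c(0L, het)); cs_mis <- cumsum(c(0L, mis))
      w_het <- cs_het[(1:n_win) + W] - cs_het[1:n_win]
      w_mis <- cs_mis[(1:n_win) + W] - cs_mis[1:n_win]
      hit <- w_het <= params$max_het_in_window &
             w_mis <= params$max_missing_in_window
      # SNP j is covered by windows max(1, j-W+1) .. min(j, n_win)
      cs_hit <- cumsum(c(0L, hit))
      j <- seq_along(vi)
      lo <- pmax(1L, j - W + 1L); hi <- pmin(j, n_win)
      hits_j <- cs_hit[hi + 1L] - cs_hit[lo]
      elig <- hits_j / (hi - lo + 1L) >= params$window_hit_threshold
      run_ok <- elig & !het
      segs <- candidate_runs(run_ok, pos, params)
      if (nrow(segs)) {
        segs$sample_id <- g$samples$sample_id[si]
        segs$population <- g$samples$population[si]
        segs$chrom <- ch
        out[[length(out) + 1]] <- segs
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), population = character(),
                      chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      length_mb = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[, c("sample_id", "population", "chrom", "start_bp", "end_bp",
          "n_snps", "length_mb")]
}

# split a logical eligibility track into reported runs
candidate_runs <- function(ok, pos, params) {
  segs <- list()
  i <- 1L; n <- length(ok)
  while (i <= n) {
    if (!ok[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && ok[j + 1L] &&
           (pos[j + 1L] - pos[j]) <= params$max_gap_kb * 1000) j <- j + 1L
    len_bp <- pos[j] - pos[i] + 1
    n_snp <- j - i + 1L
    if (n_snp >= params$min_snps &&
        len_bp >= params$min_length_kb * 1000 &&
        (len_bp / 1000) / n_snp <= params$density_kb_per_snp)
      segs[[length(segs) + 1]] <- data.frame(
        start_bp = pos[i], end_bp = pos[j], n_snps = n_snp,
        length_mb = len_bp / 1e6)
    i <- j + 1L
  }
  if (!length(segs))
    return(data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_mb = numeric()))
  do.call(rbind, segs)
}

#' Classify ROH segments by length
#'
#' Sums per-sample ROH length (Mb) in the classes 1-5, 5-10, 10-15, 15-20
#' and >20 Mb. Class intervals are half-open `[lower, upper)` so a 5.0 Mb
#' segment falls in the 5-10 class; totals conserve overall ROH length.
#'
#' @param segments segment table from [detect_roh()]
#' @return data.frame with one row per sample: class columns
#'   `mb_1_5` .. `mb_gt20` plus `total_mb`
#' @export
classify_roh <- function(segments) {
  brks <- c(0, 5, 10, 15, 20, Inf)
  lab <- c("mb_1_5", "mb_5_10", "mb_10_15", "mb_15_20", "mb_gt20")
  ids <- unique(segments$sample_id)
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (l in lab) out[[l]] <- rep(0, length(ids))
  out$total_mb <- rep(0, length(ids))
  if (!nrow(segments)) return(out)
  cls <- cut(segments$length_mb, brks, labels = lab, right = FALSE)
  for (k in seq_along(ids)) {
    sel <- segments$sample_id == ids[k]
    agg <- tapply(segments$length_mb[sel], cls[sel], sum)
    for (l in lab) if (!is.na(agg[l])) out[[l]][k] <- agg[[l]]
    out$total_mb[k] <- sum(segments$length_mb[sel])
  }
  out
}

#' Genomic inbreeding coefficients
#'
#' Computes, per sample: observed heterozygosity `Ho` (heterozygous calls /
#' non-missing calls); `F_ROH`, the fraction of the SNP-covered autosome in
#' ROH (denominator = sum over chromosomes of last - first SNP position + 1);
#' `F_GRM`, the Yang variance-standardized relationship diagonal minus one,
#' `mean_j[(x_j - 2 p_j)^2 / (2 p_j (1 - p_j))] - 1` over SNPs polymorphic in
#' the sample's population; `F_HOM = (O_hom - E_hom) / (m - E_hom)` with
#' `E_hom = sum_j (1 - 2 p_j (1 - p_j))`; and the population-level
#' `F_IS = 1 - mean(Ho_j) / mean(He_j)` (means over that population's
#' polymorphic SNPs), attached to every sample of the population. Allele
#' frequencies are always computed within the sample's own population.
#'
#' @param g a QC'd autosomal `genotype_matrix`
#' @param segments ROH table from [detect_roh()] (may be empty)
#' @return data.frame, one row per sample: `sample_id`, `population`, `Ho`,
#'   `F_ROH`, `F_GRM`, `F_HOM`, `F_IS`, `total_roh_mb` and the five class
#'   totals. `F_IS` is `NA` (with a warning) for single-sample populations.
#' @export
inbreeding_coefficients <- function(g, segments) {
  covered_bp <- sum(tapply(g$variants$pos_bp, g$variants$chrom,
                           function(p) max(p) - min(p) + 1))
  cls <- classify_roh(segments)
  n <- n_samples(g)
  res <- data.frame(sample_id = g$samples$sample_id,
                    population = g$samples$population,
                    Ho = NA_real_, F_ROH = 0, F_GRM = NA_real_,
                    F_HOM = NA_real_, F_IS = NA_real_,
                    total_roh_mb = 0, stringsAsFactors = FALSE)
  for (l in c("mb_1_5", "mb_5_10", "mb_10_15", "mb_15_20", "mb_gt20"))
    res[[l]] <- 0
  k <- match(cls$sample_id, res$sample_id)
  res$total_roh_mb[k] <- cls$total_mb
  for (l in c("mb_1_5", "mb_5_10", "mb_10_15", "mb_15_20", "mb_gt20"))
    res[[l]][k] <- cls[[l]]
  res$F_ROH <- res$total_roh_mb * 1e6 / covered_bp

  for (pop in unique(g$samples$population)) {
    si <- which(g$samples$population == pop)
    p <- allele_freq(g, pop)
    poly <- !is.na(p) & p > 0 & p < 1
    pj <- p[poly]
    for (i in si) {
      x <- g$calls[i, ]
      ok <- !is.na(x)
      res$Ho[i] <- if (any(ok)) sum(x[ok] == 1) / sum(ok) else NA_real_
      u <- ok & poly
      pu <- p[u]; xu <- x[u]
      res$F_GRM[i] <- mean((xu - 2 * pu)^2 / (2 * pu * (1 - pu))) - 1
      e_hom <- sum(1 - 2 * pu * (1 - pu))
      o_hom <- sum(xu != 1)
      res$F_HOM[i] <- (o_hom - e_hom) / (length(xu) - e_hom)
    }
    if (length(si) < 2) {
      warning("population ", pop, " has a single sample; F_IS undefined")
    } else {
      sub <- g$calls[si, poly, drop = FALSE]
      ho_j <- colMeans(sub == 1, na.rm = TRUE)
      he_j <- 2 * pj * (1 - pj)
      res$F_IS[si] <- 1 - mean(ho_j, na.rm = TRUE) / mean(he_j)
    }
  }
  res
}

#' Write ROH segments as a PLINK-style .hom table
#' @param segments segment table from [detect_roh()]
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_roh <- function(segments, path) {
  tab <- data.frame(FID = segments$population, IID = segments$sample_id,
                    CHR = segments$chrom,
                    POS1 = segments$start_bp, POS2 = segments$end_bp,
                    KB = (segments$end_bp - segments$start_bp + 1) / 1000,
                    NSNP = segments$n_snps)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
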