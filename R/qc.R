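#' Call-rate quality control
#'
#' Applies the standard SNP-array filters in a fixed order: samples whose
#' missing-call fraction exceeds `sample_max_missing` are removed first
#' (PLINK `--mind`), then variants whose missing fraction *among the
#' retained samples* exceeds `variant_max_missing` (PLINK `--geno`), then
#' non-autosomal variants are dropped. Missingness denominators always
#' exclude entities already removed, so a variant rescued by dropping a bad
#' sample is retained.
#'
#' @param g a `genotype_matrix`
#' @param sample_max_missing maximum tolerated per-sample missing fraction
#'   (default 0.10, i.e. call rate below 90\% fails).
#' @param variant_max_missing maximum tolerated per-variant missing fraction
#'   (default 0.05, i.e. call rate below 95\% fails).
#' @param autosomes_only drop variants not on autosomes 1..`n_autosomes`.
#' @param n_autosomes autosome count (26 for sheep).
#' @return list with elements `genotypes` (filtered `genotype_matrix`) and
#'   `report` (a `qc_report`: in/out counts, removal tables with missing
#'   rates, thresholds applied).
#' @export
apply_qc <- function(g, sample_max_missing = 0.10, variant_max_missing = 0.05,
                     autosomes_only = TRUE, n_autosomes = 26L) {
  stopifnot(sample_max_missing >= 0, sample_max_missing <= 1,
            variant_max_missing >= 0, variant_max_missing <= 1)
  n_in <- n_samples(g); m_in <- n_variants(g)

  smiss <- sample_missingness(g)
  bad_s <- which(smiss > sample_max_missing)
  removed_samples <- data.frame(sample_id = g$samples$sample_id[bad_s],
                                population = g$samples$population[bad_s],
                                missing_rate = unname(smiss[bad_s]),
                                stringsAsFactors = FALSE)
  if (length(bad_s) == n_in)
    stop("all samples removed at sample_max_missing = ", sample_max_missing)
  if (length(bad_s)) g <- subset_genotypes(g, samples = -bad_s)

  vmiss <- variant_missingness(g)
  bad_v <- which(vmiss > variant_max_missing)
  removed_variants <- data.frame(id = g$variants$id[bad_v],
                                 reason = rep("missingness", length(bad_v)),
                                 missing_rate = unname(vmiss[bad_v]),
                                 stringsAsFactors = FALSE)
  if (length(bad_v)) g <- subset_genotypes(g, variants = -bad_v)

  if (autosomes_only) {
    non_auto <- which(!is_autosome(g$variants$chrom, n_autosomes))
    if (length(non_auto)) {
      removed_variants <- rbind(removed_variants, data.frame(
        id = g$variants$id[non_auto], reason = "non_autosomal",
        missing_rate = unname(variant_missingness(g)[non_auto]),
        stringsAsFactors = FALSE))
      g <- subset_genotypes(g, variants = -non_auto)
    }
  }
  if (n_variants(g) == 0) stop("all variants removed by QC")

  report <- structure(list(
    n_samples_in = n_in, n_samples_out = n_samples(g),
    n_variants_in = m_in, n_variants_out = n_variants(g),
    removed_samples = removed_samples,
    removed_variants = removed_variants,
    thresholds = list(sample_max_missing = sample_max_missing,
                      variant_max_missing = variant_max_missing,
                      autosomes_only = autosomes_only)),
    class = "qc_report")
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> samples ", x$n_samples_in, " -> ", x$n_samples_out,
      "; variants ", x$n_variants_in, " -> ", x$n_variants_out, "\n", sep = "")
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_qc_report <- function(report, path) {
  rs <- report$removed_samples
  rv <- report$removed_variants
  tab <- rbind(
    data.frame(entity = rep("sample", nrow(rs)), id = rs$sample_id,
               reason = rep("missingness", nrow(rs)),
               missing_rate = rs$missing_rate),
    data.frame(entity = rep("variant", nrow(rv)), id = rv$id,
               reason = rv$reason, missing_rate = rv$missing_rate))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# squared Pearson correlation of genotype codes (composite LD, PLINK --r2),
# pairwise-complete observations
geno_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' LD pruning of variants
#'
#' Greedy sliding-window pruning of variants in high linkage
#' disequilibrium, following PLINK's `--indep-pairwise` scheme: within each
#' window of `window_snps` consecutive variants (advanced by `step_snps`,
#' windows never span chromosomes), while any retained pair has genotype
#' r-squared above `r2_threshold`, one member of the worst pair is dropped -
#' the variant with the lower minor allele frequency, ties going to the
#' later map position.
#'
#' @param g a `genotype_matrix` (QC'd)
#' @param window_snps window size in SNPs (>= 2)
#' @param step_snps step between window starts in SNPs
#' @param r2_threshold r-squared above which a pair is considered linked
#' @return integer vector of retained variant indices (ascending)
#' @export
ld_prune <- function(g, window_snps = 50L, step_snps = 5L, r2_threshold = 0.2) {
  if (window_snps < 2) stop("window_snps must be at least 2")
  stopifnot(step_snps >= 1, r2_threshold >= 0)
  keep <- rep(TRUE, n_variants(g))
  mafs <- maf(g)
  for (ch in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == ch)
    starts <- seq(1L, length(idx), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      win <- win[keep[win]]
      repeat {
        if (length(win) < 2) break
        worst <- NULL; worst_r2 <- r2_threshold
        for (a in seq_len(length(win) - 1)) {
          for (b in (a + 1):length(win)) {
            r2 <- geno_r2(g$calls[, win[a]], g$calls[, win[b]])
            if (!is.na(r2) && r2 > worst_r2) {
              worst_r2 <- r2; worst <- c(win[a], win[b])
            }
          }
        }
        if (is.null(worst)) break
        drop <- if (mafs[worst[1]] < mafs[worst[2]]) worst[1]
                else if (mafs[worst[2]] < mafs[worst[1]]) worst[2]
                else worst[2]                     # equal MAF: later position
        keep[drop] <- FALSE
        win <- win[win != drop]
      }
    }
  }
  which(keep)
}

#' Variance-standardized genomic relationship matrix
#'
#' Yang-style GRM: `G[i,k] = mean_j (x_ij - 2 p_j)(x_kj - 2 p_j) /
#' (2 p_j (1 - p_j))` over non-monomorphic SNPs, with missing genotypes
#' dropped pairwise. Frequencies are computed from the supplied samples.
#'
#' @param g a `genotype_matrix`
#' @return symmetric numeric matrix, samples x samples
#' @export
grm <- function(g) {
  p <- allele_freq(g)
  poly <- which(!is.na(p) & p > 0 & p < 1)
  if (!length(poly)) stop("no polymorphic SNPs: relationship undefined")
  x <- g$calls[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(x, 2, 2 * p)                 # x - 2p, NA propagated
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  zf <- z; zf[is.na(zf)] <- 0
  obs <- (!is.na(z)) * 1
  num <- tcrossprod(zf)
  den <- tcrossprod(obs)                  # SNPs observed in both samples
  out <- num / den
  dimnames(out) <- list(g$samples$sample_id, g$samples$sample_id)
  out
}

#' Remove close relatives
#'
#' Flags sample pairs whose within-population genomic relatedness (GRM
#' off-diagonal) exceeds `threshold` and greedily removes, from each flagged
#' pair, the member involved in more flagged pairs (ties removing the
#' later-listed sample), until no flagged pair remains.
#'
#' @param g a `genotype_matrix`
#' @param threshold relatedness above which a pair is flagged (0.25 by
#'   default, i.e. closer than second-degree relatives)
#' @return character vector of retained sample ids, in input order
#' @export
kinship_filter <- function(g, threshold = 0.25) {
  ids <- g$samples$sample_id
  flagged <- matrix(FALSE, length(ids), length(ids))
  for (pop in unique(g$samples$population)) {
    si <- which(g$samples$population == pop)
    if (length(si) < 2) next
    G <- grm(subset_genotypes(g, samples = si))
    for (a in seq_len(length(si) - 1))
      for (b in (a + 1):length(si))
        if (!is.na(G[a, b]) && G[a, b] > threshold)
          flagged[si[a], si[b]] <- flagged[si[b], si[a]] <- TRUE
  }
  removed <- logical(length(ids))
  repeat {
    deg <- rowSums(flagged)
    if (max(deg) == 0) break
    victim <- max(which(deg == max(deg)))   # tie: later sample
    removed[victim] <- TRUE
    flagged[victim, ] <- flagged[, victim] <- FALSE
  }
  ids[!removed]
}
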