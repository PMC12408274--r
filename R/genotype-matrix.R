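#' Construct a genotype matrix
#'
#' The central data container of the package: a samples x variants matrix of
#' diploid genotype codes together with the variant map and per-sample
#' population labels. Codes count copies of the `a2` allele: `0` = a1/a1
#' homozygote, `1` = heterozygote, `2` = a2/a2 homozygote, `NA` = missing.
#' For text PLINK input `a1` is the minor allele determined at load time, so
#' code 2 counts the major allele; for binary input `a1` is taken from the
#' BIM file as written.
#'
#' @param calls integer matrix, `n_samples x n_variants`, entries in
#'   `{0, 1, 2, NA}`.
#' @param samples data.frame with columns `sample_id` (unique) and
#'   `population`.
#' @param variants data.frame with columns `chrom`, `pos_bp` (1-based),
#'   `id`, `a1`, `a2`; rows sorted by (chrom, pos_bp) within each chromosome
#'   block.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples, variants) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(samples), is.data.frame(variants))
  if (nrow(calls) != nrow(samples))
    stop("calls has ", nrow(calls), " rows but ", nrow(samples), " samples")
  if (ncol(calls) != nrow(variants))
    stop("calls has ", ncol(calls), " columns but ", nrow(variants),
         " variants")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in samples table")
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad)) stop("genotype codes outside {0,1,2,NA}")
  if (any(variants$pos_bp <= 0)) stop("variant positions must be positive")
  if (any(variants$a1 == variants$a2))
    stop("monomorphic allele pair (a1 == a2) for variant ",
         variants$id[which(variants$a1 == variants$a2)[1]])
  # positions must be non-decreasing within each chromosome block
  for (ch in unique(variants$chrom)) {
    p <- variants$pos_bp[variants$chrom == ch]
    if (is.unsorted(p)) stop("variants not sorted by position on chromosome ", ch)
  }
  rownames(calls) <- samples$sample_id
  colnames(calls) <- variants$id
  structure(list(calls = calls,
                 samples = as.data.frame(samples, stringsAsFactors = FALSE),
                 variants = as.data.frame(variants, stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$calls), " samples x ", ncol(x$calls),
      " variants\n", sep = "")
  cat("  populations: ",
      paste(sprintf("%s(%d)", names(table(x$samples$population)),
                    table(x$samples$population)), collapse = ", "), "\n",
      sep = "")
  cat("  chromosomes: ", length(unique(x$variants$chrom)),
      "; missing rate: ",
      signif(mean(is.na(x$calls)), 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of samples / variants
#' @param g a `genotype_matrix`
#' @return integer count
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname n_samples
#' @export
n_variants <- function(g) ncol(g$calls)

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`
#' @param samples index vector into the sample table (integer, logical or
#'   sample_id character), or NULL to keep all.
#' @param variants index vector into the variant table, or NULL.
#' @return the subsetted `genotype_matrix`
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(g)) else samples
  if (is.character(si)) si <- match(si, g$samples$sample_id)
  vi <- if (is.null(variants)) seq_len(n_variants(g)) else variants
  if (is.character(vi)) vi <- match(vi, g$variants$id)
  genotype_matrix(g$calls[si, vi, drop = FALSE],
                  g$samples[si, , drop = FALSE],
                  g$variants[vi, , drop = FALSE])
}

#' Allele frequencies of the a2 allele
#'
#' @param g a `genotype_matrix`
#' @param population optional label; frequencies computed on that
#'   population's samples only.
#' @return numeric vector, one frequency per variant (`NaN` where every call
#'   is missing).
#' @export
allele_freq <- function(g, population = NULL) {
  m <- g$calls
  if (!is.null(population)) {
    keep <- g$samples$population == population
    if (!any(keep)) stop("unknown population: ", population)
    m <- m[keep, , drop = FALSE]
  }
  colMeans(m, na.rm = TRUE) / 2
}

#' Per-variant and per-sample missingness
#' @param g a `genotype_matrix`
#' @return numeric vector of missing-call fractions
#' @export
variant_missingness <- function(g) colMeans(is.na(g$calls))

#' @rdname variant_missingness
#' @export
sample_missingness <- function(g) rowMeans(is.na(g$calls))

#' Minor allele frequency per variant
#' @param g a `genotype_matrix`
#' @param population optional population restriction
#' @return numeric vector in `[0, 0.5]`
#' @export
maf <- function(g, population = NULL) {
  p <- allele_freq(g, population)
  pmin(p, 1 - p)
}

# Sheep autosomes are labelled 1..26; anything else (X, Y, MT, 0, contigs)
# is treated as non-autosomal.
is_autosome <- function(chrom, n_autosomes = 26L) {
  suppressWarnings(ci <- as.integer(as.character(chrom)))
  !is.na(ci) & ci >= 1L & ci <= n_autosomes
}
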