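#' Construct a phased haplotype set
#'
#' Phased 0/1 alleles for one chromosome: a gametes x sites matrix with two
#' consecutive rows per diploid sample. No missing alleles are allowed
#' (phased-input contract).
#'
#' @param chrom chromosome label
#' @param positions_bp strictly increasing 1-based positions
#' @param haplotypes matrix of 0/1 alleles, `2 * n_samples` rows
#' @param sample_ids character vector, length `nrow(haplotypes)/2`; gametes
#'   `2k-1` and `2k` belong to sample `k`
#' @return object of class `haplotype_set`
#' @export
haplotype_set <- function(chrom, positions_bp, haplotypes, sample_ids) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (anyNA(haplotypes)) stop("phased haplotypes must not contain missing alleles")
  if (!all(haplotypes %in% 0:1)) stop("haplotype alleles must be 0/1")
  if (ncol(haplotypes) != length(positions_bp))
    stop("haplotype columns do not align with positions")
  if (is.unsorted(positions_bp, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (nrow(haplotypes) != 2 * length(sample_ids))
    stop("need exactly two gametes per sample")
  structure(list(chrom = chrom, positions_bp = as.numeric(positions_bp),
                 haplotypes = haplotypes, sample_ids = sample_ids),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> chromosome ", x$chrom, ": ",
      nrow(x$haplotypes), " gametes x ", ncol(x$haplotypes), " sites\n",
      sep = "")
  invisible(x)
}

#' Write phased haplotypes to VCF
#'
#' Emits a minimal VCF 4.2 file with phased `GT` fields (`0|1` style), one
#' file for any number of chromosomes. REF is the 0 allele, ALT the 1
#' allele.
#'
#' @param hsets a `haplotype_set` or list of them (same samples, one per
#'   chromosome)
#' @param path output `.vcf` path
#' @param ref,alt allele letters used for REF/ALT (defaults A/B are
#'   placeholder array alleles)
#' @return invisibly, `path`
#' @export
write_phased_vcf <- function(hsets, path, ref = "A", alt = "B") {
  if (inherits(hsets, "haplotype_set")) hsets <- list(hsets)
  ids <- hsets[[1]]$sample_ids
  hdr <- c("##fileformat=VCFv4.2",
           "##source=flockscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- unlist(lapply(hsets, function(h) {
    stopifnot(identical(h$sample_ids, ids))
    n <- length(ids)
    gt <- matrix("", length(h$positions_bp), n)
    for (k in seq_len(n))
      gt[, k] <- paste0(h$haplotypes[2 * k - 1, ], "|", h$haplotypes[2 * k, ])
    ident <- paste0("snp_", h$chrom, "_", format(h$positions_bp,
                                                 scientific = FALSE,
                                                 trim = TRUE))
    apply(cbind(h$chrom, format(h$positions_bp, scientific = FALSE,
                                trim = TRUE),
                ident, ref, alt, ".", "PASS", ".", "GT", gt),
          1, paste, collapse = "\t")
  }))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read phased haplotypes from VCF
#'
#' Reads a phased VCF (via the `vcfR` parser) into one `haplotype_set` per
#' chromosome. All `GT` fields must be phased and complete; biallelic sites
#' only.
#'
#' @param path VCF file path
#' @return named list of `haplotype_set`, one per chromosome in file order
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  if (any(!grepl("^[01]\\|[01]$", gt)))
    stop("VCF contains unphased, missing or multiallelic GT fields")
  ids <- colnames(gt)
  chroms <- unique(fix[, "CHROM"])
  out <- list()
  for (ch in chroms) {
    rows <- which(fix[, "CHROM"] == ch)
    pos <- as.numeric(fix[rows, "POS"])
    H <- matrix(0L, 2 * length(ids), length(rows))
    for (k in seq_along(ids)) {
      parts <- strsplit(gt[rows, k], "|", fixed = TRUE)
      H[2 * k - 1, ] <- as.integer(vapply(parts, `[`, "", 1))
      H[2 * k, ] <- as.integer(vapply(parts, `[`, "", 2))
    }
    out[[as.character(ch)]] <- haplotype_set(ch, pos, H, ids)
  }
  out
}

#' Collapse phased haplotypes to genotype codes
#'
#' @param hsets list of `haplotype_set` (one per chromosome)
#' @param populations named character vector mapping sample_id to
#'   population label (defaults to a single population `"pop1"`)
#' @return a `genotype_matrix` whose a2 allele is the haplotype 1 allele
#' @export
haplotypes_to_genotypes <- function(hsets, populations = NULL) {
  if (inherits(hsets, "haplotype_set")) hsets <- list(hsets)
  ids <- hsets[[1]]$sample_ids
  if (is.null(populations))
    populations <- stats::setNames(rep("pop1", length(ids)), ids)
  calls <- NULL; vars <- NULL
  for (h in hsets) {
    n <- length(ids)
    odd <- h$haplotypes[2 * seq_len(n) - 1, , drop = FALSE]
    evn <- h$haplotypes[2 * seq_len(n), , drop = FALSE]
    calls <- cbind(calls, odd + evn)
    vars <- rbind(vars, data.frame(
      chrom = h$chrom, pos_bp = h$positions_bp,
      id = paste0("snp_", h$chrom, "_", format(h$positions_bp,
                                               scientific = FALSE,
                                               trim = TRUE)),
      a1 = "A", a2 = "B", stringsAsFactors = FALSE))
  }
  genotype_matrix(calls,
                  data.frame(sample_id = ids,
                             population = unname(populations[ids]),
                             stringsAsFactors = FALSE),
                  vars)
}

#' Subset a haplotype set to chosen samples
#' @param h a `haplotype_set`
#' @param sample_ids samples to keep
#' @return a `haplotype_set`
#' @export
subset_haplotypes <- function(h, sample_ids) {
  k <- match(sample_ids, h$sample_ids)
  if (anyNA(k)) stop("unknown sample ids")
  rows <- as.vector(rbind(2 * k - 1, 2 * k))
  haplotype_set(h$chrom, h$positions_bp, h$haplotypes[rows, , drop = FALSE],
                h$sample_ids[k])
}
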