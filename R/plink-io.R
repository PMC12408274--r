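#' Read PLINK genotype files
#'
#' Reads either text (PED/MAP) or binary (BED/BIM/FAM, SNP-major) PLINK 1.9
#' file sets into a [genotype_matrix()].
#'
#' For text input the a1 allele of each variant is the minor allele computed
#' from the data (frequency tie broken towards the alphabetically smaller
#' allele), matching the PLINK convention of coding against the minor
#' allele. For binary input a1 is the first allele column of the BIM file,
#' as written.
#'
#' @param prefix path prefix; `<prefix>.ped/.map` or `<prefix>.bed/.bim/.fam`
#'   must exist.
#' @param format `"text"`, `"binary"`, or `"auto"` (binary preferred when
#'   both file sets are present).
#' @return a `genotype_matrix`
#' @export
load_plink <- function(prefix, format = c("auto", "text", "binary")) {
  format <- match.arg(format)
  has_bin <- file.exists(paste0(prefix, ".bed"))
  has_txt <- file.exists(paste0(prefix, ".ped"))
  if (format == "auto") format <- if (has_bin) "binary" else "text"
  if (format == "binary" && !has_bin)
    stop("no BED file at prefix ", prefix)
  if (format == "text" && !has_txt)
    stop("no PED file at prefix ", prefix)
  if (format == "binary") read_bed(prefix) else read_ped(prefix)
}

read_map_like <- function(path) {
  mp <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(mp) < 4) stop("malformed map file: ", path)
  data.frame(chrom = mp[[1]], id = mp[[2]],
             pos_bp = as.numeric(mp[[4]]), stringsAsFactors = FALSE)
}

read_ped <- function(prefix) {
  map <- read_map_like(paste0(prefix, ".map"))
  lines <- readLines(paste0(prefix, ".ped"))
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  m <- nrow(map)
  fields <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(fields)
  if (any(len != 6 + 2 * m))
    stop("PED record length mismatch: expected ", 6 + 2 * m,
         " fields, got ", len[which(len != 6 + 2 * m)[1]],
         " (map and genotype records disagree)")
  ped <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  samples <- data.frame(sample_id = ped[, 2], population = ped[, 1],
                        stringsAsFactors = FALSE)
  al1 <- ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  al2 <- ped[, 6 + 2 * seq_len(m), drop = FALSE]
  calls <- matrix(NA_integer_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    obs <- c(al1[, j], al2[, j])
    obs <- obs[obs != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stop("variant ", map$id[j], " is not biallelic (alleles: ",
           paste(alleles, collapse = ","), ")")
    if (length(alleles) == 0) alleles <- c("A", "B")      # all-missing column
    if (length(alleles) == 1) alleles <- c(alleles, if (alleles == "B") "A" else "B")
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    # minor allele becomes a1; tie already resolved by the sort() above
    if (cnt[2] < cnt[1]) alleles <- rev(alleles)
    a1[j] <- alleles[1]; a2[j] <- alleles[2]
    miss <- al1[, j] == "0" | al2[, j] == "0"
    calls[, j] <- (al1[, j] == a2[j]) + (al2[, j] == a2[j])
    calls[miss, j] <- NA_integer_
  }
  variants <- data.frame(chrom = map$chrom, pos_bp = map$pos_bp, id = map$id,
                         a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  genotype_matrix(calls, samples, variants)
}

# PLINK 1.9 BED: magic 0x6c 0x1b, mode 0x01 (SNP-major); per variant
# ceiling(n/4) bytes, two bits per sample, LSB first:
# 00 = hom a1, 01 = missing, 10 = het, 11 = hom a2.
read_bed <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  samples <- data.frame(sample_id = fam[[2]], population = fam[[1]],
                        stringsAsFactors = FALSE)
  variants <- data.frame(chrom = bim[[1]], pos_bp = as.numeric(bim[[4]]),
                         id = bim[[2]], a1 = bim[[5]], a2 = bim[[6]],
                         stringsAsFactors = FALSE)
  bytes_per_var <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = 3 + bytes_per_var * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes): ", prefix, ".bed")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major BED files are supported")
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_var * m)
    stop("BED payload size does not match FAM x BIM dimensions")
  # expand every byte into its four 2-bit fields, then trim to n per variant
  ints <- as.integer(body)
  two_bits <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                    (ints %/% 16L) %% 4L, ints %/% 64L)
  per_var <- matrix(as.vector(two_bits), nrow = 4 * bytes_per_var, ncol = m)
  per_var <- per_var[seq_len(n), , drop = FALSE]
  lut <- c(0L, NA_integer_, 1L, 2L)         # indexed by 2-bit code + 1
  calls <- matrix(lut[per_var + 1L], n, m)
  genotype_matrix(calls, samples, variants)
}

#' Write PLINK genotype files
#'
#' @param g a non-empty `genotype_matrix`
#' @param prefix output path prefix
#' @param format `"text"` (PED/MAP) or `"binary"` (BED/BIM/FAM, SNP-major)
#' @return invisibly, the character vector of files written
#' @export
save_plink <- function(g, prefix, format = c("text", "binary")) {
  format <- match.arg(format)
  if (n_variants(g) == 0 || n_samples(g) == 0)
    stop("refusing to write an empty genotype matrix")
  if (format == "text") write_ped(g, prefix) else write_bed(g, prefix)
}

write_ped <- function(g, prefix) {
  v <- g$variants
  map <- paste(v$chrom, v$id, 0, format(v$pos_bp, scientific = FALSE,
                                        trim = TRUE), sep = "\t")
  writeLines(map, paste0(prefix, ".map"))
  n <- n_samples(g); m <- n_variants(g)
  a1m <- matrix(v$a1, n, m, byrow = TRUE)
  a2m <- matrix(v$a2, n, m, byrow = TRUE)
  first <- ifelse(is.na(g$calls), "0", ifelse(g$calls >= 1, a2m, a1m))
  second <- ifelse(is.na(g$calls), "0", ifelse(g$calls == 2, a2m, a1m))
  geno <- matrix("", n, 2 * m)
  geno[, 2 * seq_len(m) - 1] <- first
  geno[, 2 * seq_len(m)] <- second
  lead <- cbind(g$samples$population, g$samples$sample_id, "0", "0", "0", "-9")
  writeLines(apply(cbind(lead, geno), 1, paste, collapse = " "),
             paste0(prefix, ".ped"))
  invisible(paste0(prefix, c(".ped", ".map")))
}

write_bed <- function(g, prefix) {
  v <- g$variants
  utils::write.table(
    cbind(g$samples$population, g$samples$sample_id, 0, 0, 0, -9),
    paste0(prefix, ".fam"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = " ")
  utils::write.table(
    cbind(v$chrom, v$id, 0, format(v$pos_bp, scientific = FALSE, trim = TRUE),
          v$a1, v$a2),
    paste0(prefix, ".bim"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  n <- n_samples(g); m <- n_variants(g)
  code <- matrix(0L, n, m)                       # 2-bit field per call
  code[is.na(g$calls)] <- 1L
  code[!is.na(g$calls) & g$calls == 1L] <- 2L
  code[!is.na(g$calls) & g$calls == 2L] <- 3L
  bytes_per_var <- ceiling(n / 4)
  padded <- matrix(0L, 4 * bytes_per_var, m)
  padded[seq_len(n), ] <- code
  idx <- seq(1, 4 * bytes_per_var, by = 4)
  byte_vals <- padded[idx, , drop = FALSE] +
    4L * padded[idx + 1, , drop = FALSE] +
    16L * padded[idx + 2, , drop = FALSE] +
    64L * padded[idx + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(byte_vals)), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
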