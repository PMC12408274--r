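#' Weir-Cockerham FST between two populations
#'
#' Method-of-moments estimator of the fixation index from the Weir &
#' Cockerham (1984) variance components. Per biallelic SNP, with `r = 2`
#' populations of sample sizes `n_i` (individuals with non-missing calls),
#' allele frequencies `p_i` and observed heterozygote proportions `h_i`:
#'
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'   \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'   \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right]}
#' \deqn{c = \bar h / 2}
#'
#' with per-SNP `theta = a/(a+b+c)` and the genome-wide mean the ratio of
#' sums `sum(a)/sum(a+b+c)`. Negative estimates (sampling noise) are kept in
#' the `theta_raw` column and clamped to zero in `theta`; the mean is
#' clamped independently of the per-SNP values.
#'
#' @param g a `genotype_matrix`
#' @param pop_a,pop_b population labels present in `g`
#' @return list of class `fst_result`: `population_pair`, `per_snp`
#'   (data.frame `id`, `chrom`, `pos_bp`, `theta_raw`, `theta`),
#'   `mean_fst` (clamped), `mean_fst_raw`
#' @export
wc_fst <- function(g, pop_a, pop_b) {
  for (p in c(pop_a, pop_b))
    if (!p %in% g$samples$population) stop("unknown population: ", p)
  ia <- which(g$samples$population == pop_a)
  ib <- which(g$samples$population == pop_b)
  A <- g$calls[ia, , drop = FALSE]
  B <- g$calls[ib, , drop = FALSE]
  na_j <- colSums(!is.na(A)); nb_j <- colSums(!is.na(B))
  pa <- colMeans(A, na.rm = TRUE) / 2
  pb <- colMeans(B, na.rm = TRUE) / 2
  ha <- colMeans(A == 1, na.rm = TRUE)
  hb <- colMeans(B == 1, na.rm = TRUE)
  use <- na_j >= 2 & nb_j >= 2 & !(pa %in% c(0, 1) & pb == pa)
  r <- 2
  nbar <- (na_j + nb_j) / r
  nc <- (r * nbar - (na_j^2 + nb_j^2) / (r * nbar)) / (r - 1)
  pbar <- (na_j * pa + nb_j * pb) / (r * nbar)
  s2 <- (na_j * (pa - pbar)^2 + nb_j * (pb - pbar)^2) / ((r - 1) * nbar)
  hbar <- (na_j * ha + nb_j * hb) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  use <- use & !is.na(tot) & tot != 0
  theta_raw <- ifelse(use, a / tot, NA_real_)
  per_snp <- data.frame(id = g$variants$id, chrom = g$variants$chrom,
                        pos_bp = g$variants$pos_bp,
                        theta_raw = theta_raw,
                        theta = pmax(theta_raw, 0),
                        stringsAsFactors = FALSE)
  mean_raw <- sum(a[use]) / sum(tot[use])
  structure(list(population_pair = c(pop_a, pop_b),
                 per_snp = per_snp,
                 mean_fst = max(mean_raw, 0),
                 mean_fst_raw = mean_raw),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> ", x$population_pair[1], " vs ", x$population_pair[2],
      ": mean FST = ", signif(x$mean_fst, 4), " (",
      sum(!is.na(x$per_snp$theta_raw)), " SNPs)\n", sep = "")
  invisible(x)
}

#' Pairwise FST matrix over all populations
#'
#' @param g a `genotype_matrix`
#' @return symmetric numeric matrix of clamped ratio-of-sums mean FST,
#'   zero diagonal
#' @export
fst_matrix <- function(g) {
  pops <- unique(g$samples$population)
  M <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (length(pops) < 2) return(M)
  for (a in seq_len(length(pops) - 1))
    for (b in (a + 1):length(pops)) {
      f <- wc_fst(g, pops[a], pops[b])$mean_fst
      M[a, b] <- M[b, a] <- f
    }
  M
}
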