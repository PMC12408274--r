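#' Genetic mapping functions
#'
#' Convert a physical distance (in Morgans under a constant cM/Mb rate)
#' into an effective recombination rate `c`. `linear` is the identity
#' (`c = d`); `sved_feldman` applies the hyperbolic shrinkage
#' `c = d / (1 + 2 d)`, which accounts for the non-linearity between map
#' distance and recombination fraction at longer ranges and is the
#' correction used by LD-based Ne tools.
#'
#' @param d distance in Morgans
#' @return recombination rate (Morgans)
#' @export
map_linear <- function(d) d

#' @rdname map_linear
#' @export
map_sved_feldman <- function(d) d / (1 + 2 * d)

#' LD-decay historical effective population size
#'
#' Bins within-chromosome SNP pairs by physical distance, averages the
#' squared genotype correlation (composite r-squared) per bin, corrects for
#' chromosome sample size, and inverts the Sved drift-recombination
#' expectation to an effective population size per bin:
#' \deqn{r^2_{adj} = \bar{r}^2 - 1/(\beta n), \quad
#'   N_e = \frac{1}{4 f(c)}\left(\frac{1}{r^2_{adj}} - \alpha\right), \quad
#'   t = \frac{1}{2 f(c)}}
#' where `c` is the mapped recombination rate at the bin midpoint, `alpha`
#' absorbs mutation (2 by default) and `beta` is 2 for unphased genotype
#' data (1 for phased). Larger distances inform more recent generations.
#' Input should already be LD-pruned with the stringent Ne settings
#' (100-SNP window, step 50, r2 < 0.1) by the caller.
#'
#' @param g a `genotype_matrix` (typically one population, pruned)
#' @param dist_min_bp,dist_max_bp distance range for pairs (default 50 kb to
#'   4 Mb)
#' @param bin_bp bin width (default 50 kb)
#' @param alpha mutation parameter (default 2)
#' @param mapping `"sved_feldman"` (default) or `"linear"`
#' @param beta `"unphased"` (correction `1/(2n)`, default) or `"phased"`
#'   (`1/n`)
#' @param cm_per_mb assumed constant recombination rate (default 1 cM/Mb)
#' @return data.frame of class `ne_trajectory`, one row per bin:
#'   `dist_lo_bp`, `dist_hi_bp`, `n_pairs`, `mean_r2`, `mean_r2_adj`,
#'   `c_morgans`, `Ne`, `t_generations`, `valid`. Bins with no pairs or
#'   non-positive adjusted r-squared carry `NA` Ne and `valid = FALSE`.
#' @export
ne_trajectory <- function(g, dist_min_bp = 50000, dist_max_bp = 4000000,
                          bin_bp = 50000, alpha = 2,
                          mapping = c("sved_feldman", "linear"),
                          beta = c("unphased", "phased"), cm_per_mb = 1.0) {
  mapping <- match.arg(mapping)
  beta <- match.arg(beta)
  fmap <- if (mapping == "linear") map_linear else map_sved_feldman
  bcoef <- if (beta == "unphased") 2 else 1
  edges <- seq(dist_min_bp, dist_max_bp, by = bin_bp)
  nb <- length(edges) - 1L
  sum_r2 <- numeric(nb); n_pairs <- integer(nb); n_used <- numeric(nb)
  for (ch in unique(g$variants$chrom)) {
    vi <- which(g$variants$chrom == ch)
    pos <- g$variants$pos_bp[vi]
    for (a in seq_along(vi)) {
      bmax <- which(pos - pos[a] > dist_max_bp)[1]
      bhi <- if (is.na(bmax)) length(vi) else bmax - 1L
      if (bhi <= a) next
      for (b in (a + 1):bhi) {
        d <- pos[b] - pos[a]
        if (d < dist_min_bp) next
        x <- g$calls[, vi[a]]; y <- g$calls[, vi[b]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 4) next
        sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
        if (sx == 0 || sy == 0) next
        k <- min(floor((d - dist_min_bp) / bin_bp) + 1L, nb)
        sum_r2[k] <- sum_r2[k] + stats::cor(x[ok], y[ok])^2
        n_pairs[k] <- n_pairs[k] + 1L
        n_used[k] <- n_used[k] + sum(ok)
      }
    }
  }
  mid <- (edges[-(nb + 1)] + edges[-1]) / 2
  mean_r2 <- ifelse(n_pairs > 0, sum_r2 / n_pairs, NA_real_)
  n_eff <- ifelse(n_pairs > 0, n_used / n_pairs, NA_real_)
  r2_adj <- mean_r2 - 1 / (bcoef * n_eff)
  cM <- fmap(mid * cm_per_mb * 1e-8)
  Ne <- ifelse(!is.na(r2_adj) & r2_adj > 0 & (1 / r2_adj - alpha) > 0,
               (1 / (4 * cM)) * (1 / r2_adj - alpha), NA_real_)
  res <- data.frame(dist_lo_bp = edges[-(nb + 1)], dist_hi_bp = edges[-1],
                    n_pairs = n_pairs, mean_r2 = mean_r2,
                    mean_r2_adj = r2_adj, c_morgans = cM, Ne = Ne,
                    t_generations = floor(1 / (2 * cM) + 0.5),
                    valid = !is.na(Ne))
  class(res) <- c("ne_trajectory", "data.frame")
  attr(res, "alpha") <- alpha
  attr(res, "mapping") <- mapping
  attr(res, "beta") <- beta
  res
}

#' Point arithmetic of the Sved Ne inversion
#'
#' Exposes the bin-level computation used by [ne_trajectory()]:
#' `Ne = (1/(4 f_c)) * (1/r2_adj - alpha)` and `t = 1/(2 f_c)` generations
#' (rounded half up).
#'
#' @param r2_adj sample-size-adjusted mean r-squared
#' @param f_c mapped recombination rate in Morgans
#' @param alpha mutation parameter
#' @return list with `Ne` and `t_generations`
#' @export
ne_from_r2 <- function(r2_adj, f_c, alpha = 2) {
  if (r2_adj <= 0 || 1 / r2_adj - alpha <= 0)
    return(list(Ne = NA_real_, t_generations = floor(1 / (2 * f_c) + 0.5)))
  list(Ne = (1 / (4 * f_c)) * (1 / r2_adj - alpha),
       t_generations = floor(1 / (2 * f_c) + 0.5))
}
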