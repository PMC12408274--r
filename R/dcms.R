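#' Running-median smoothing
#'
#' Width-`width` running median with shrinking windows at the edges (the
#' window is truncated to the available neighbours), so the output has the
#' length of the input. Width 1 is the identity.
#'
#' @param x numeric vector
#' @param width odd window width (default 3)
#' @return smoothed numeric vector
#' @export
median_smooth <- function(x, width = 3L) {
  stopifnot(width >= 1, width %% 2 == 1)
  if (width == 1 || length(x) < 2) return(x)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - half):min(n, i + half)], na.rm = TRUE)
  }, 0)
}

#' Merge native-resolution scores onto a common window grid
#'
#' Assigns each score to the non-overlapping `grid_bp` window containing
#' its midpoint (half-open windows: a midpoint landing exactly on a
#' boundary belongs to the following window) and averages scores per
#' window. Site-level statistics use the site position as midpoint; window
#' statistics use `(start + end)/2`. The iHS series contributes the
#' absolute standardized score, optionally median-smoothed first.
#'
#' @param stats_list named list of data.frames; site-level entries need
#'   `chrom`, `pos_bp`, `value`; window-level entries `chrom`, `start_bp`,
#'   `end_bp`, `value`
#' @param grid_bp grid window size (default 500 kb)
#' @return data.frame with `chrom`, `start_bp`, `end_bp` and one mean-value
#'   column per input statistic (NA where no score fell in the window)
#' @export
aggregate_to_grid <- function(stats_list, grid_bp = 500000) {
  pieces <- lapply(names(stats_list), function(nm) {
    df <- stats_list[[nm]]
    if (!nrow(df)) return(NULL)
    mid <- if ("pos_bp" %in% names(df)) df$pos_bp
           else (df$start_bp + df$end_bp) / 2
    data.frame(chrom = df$chrom, win = floor(mid / grid_bp),
               stat = nm, value = df$value, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, pieces)
  long <- long[!is.na(long$value), , drop = FALSE]
  if (!nrow(long)) stop("no scores to aggregate")
  key <- paste(long$chrom, long$win, sep = ":")
  cells <- tapply(long$value, list(key, long$stat), mean)
  keys <- rownames(cells)
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    win = as.numeric(vapply(parts, `[`, "", 2)),
                    stringsAsFactors = FALSE)
  for (nm in colnames(cells)) out[[nm]] <- as.vector(cells[, nm])
  out$start_bp <- out$win * grid_bp + 1
  out$end_bp <- (out$win + 1) * grid_bp
  out <- out[order(out$chrom, out$start_bp), ]
  rownames(out) <- NULL
  out[, c("chrom", "start_bp", "end_bp", names(stats_list)[
    names(stats_list) %in% colnames(cells)])]
}

#' Rank-transform a statistic to tail-specific empirical p-values
#'
#' Average ranks handle ties; with `N` non-missing values,
#' right tail: `p = (N - rank + 1)/(N + 1)` (large values small p);
#' left tail: `p = rank/(N + 1)` (small values small p). Resulting p lie
#' strictly inside (0, 1). Missing values stay missing.
#'
#' @param values numeric vector (>= 2 non-missing)
#' @param tail `"right"` or `"left"`
#' @return numeric vector of p-values
#' @export
rank_to_p <- function(values, tail = c("right", "left")) {
  tail <- match.arg(tail)
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values to rank")
  r <- rank(values[ok], ties.method = "average")
  N <- sum(ok)
  p <- rep(NA_real_, length(values))
  p[ok] <- if (tail == "right") (N - r + 1) / (N + 1) else r / (N + 1)
  p
}

#' Decorrelated composite of multiple signals
#'
#' Combines the per-window p-values of several statistics into one
#' composite score while discounting redundant (correlated) statistics.
#' With `r_ik` the Pearson correlation between the p-value series of
#' statistics `i` and `k` (pairwise-complete windows, `r_ii = 1`), each
#' statistic receives weight `w_i = 1 / sum_k |r_ik|`, and
#' `DCMS_j = sum_i w_i log10((1 - p_ij) / p_ij)` over the statistics
#' available in window `j`. Windows with fewer than `min_components`
#' p-values are excluded; when some components are missing, the available
#' weights are rescaled so they sum to the full-set weight total, keeping
#' scores on a comparable scale.
#'
#' @param p_table data.frame from [aggregate_to_grid()] columns `chrom`,
#'   `start_bp`, `end_bp` plus one p-value column per statistic
#' @param min_components minimum statistics per scored window (default 3)
#' @return data.frame of class `dcms_windows`: the input windows (scored
#'   rows only) with a `dcms` column; attribute `weights` carries the
#'   per-statistic weights and `correlation` the correlation matrix
#' @export
dcms_scores <- function(p_table, min_components = 3L) {
  stat_cols <- setdiff(names(p_table), c("chrom", "start_bp", "end_bp"))
  P <- as.matrix(p_table[, stat_cols, drop = FALSE])
  if (any(P <= 0 | P >= 1, na.rm = TRUE))
    stop("p-values must lie strictly inside (0, 1)")
  n_avail <- rowSums(!is.na(P))
  scored <- n_avail >= min(min_components, length(stat_cols))
  if (sum(scored) < 10)
    stop("fewer than 10 scored windows genome-wide; refusing to calibrate")
  R <- suppressWarnings(stats::cor(P, use = "pairwise.complete.obs"))
  R[is.na(R)] <- 0; diag(R) <- 1
  w <- 1 / rowSums(abs(R))
  wsum <- sum(w)
  logit10 <- log10((1 - P) / P)
  dcms <- rep(NA_real_, nrow(P))
  for (j in which(scored)) {
    av <- which(!is.na(P[j, ]))
    wj <- w[av] * wsum / sum(w[av])
    dcms[j] <- sum(wj * logit10[j, av])
  }
  out <- p_table[scored, , drop = FALSE]
  out$dcms <- dcms[scored]
  rownames(out) <- NULL
  class(out) <- c("dcms_windows", "data.frame")
  attr(out, "weights") <- w
  attr(out, "correlation") <- R
  out
}

#' Gaussian calibration and FDR significance of DCMS scores
#'
#' Standardizes the composite scores against a normal distribution with the
#' sample mean and standard deviation, converts to upper-tail p-values
#' (high DCMS = selection candidate), applies Benjamini-Hochberg step-up
#' adjustment and flags windows with `q < fdr_q`.
#'
#' @param windows a `dcms_windows` table (>= 10 windows)
#' @param fdr_q FDR threshold (default 0.05)
#' @return the table with added `p_normal`, `q`, `significant` columns
#' @export
significance_call <- function(windows, fdr_q = 0.05) {
  if (nrow(windows) < 10) stop("need at least 10 scored windows")
  mu <- mean(windows$dcms); sg <- stats::sd(windows$dcms)
  if (sg == 0) stop("zero variance in DCMS scores; calibration impossible")
  windows$p_normal <- stats::pnorm((windows$dcms - mu) / sg,
                                   lower.tail = FALSE)
  windows$q <- stats::p.adjust(windows$p_normal, method = "BH")
  windows$significant <- windows$q < fdr_q
  windows
}

#' Export significant windows as flanked, merged BED records
#'
#' Significant windows are extended by `flank_bp` on each side, converted
#' to 0-based half-open BED coordinates, clipped at chromosome bounds and
#' merged when overlapping or touching.
#'
#' @param windows output of [significance_call()]
#' @param flank_bp flank added on each side (default 500 kb)
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   right-clipping
#' @param path optional output file; when given the records are written as
#'   3-column BED
#' @return data.frame `chrom`, `start` (0-based), `end` (exclusive)
#' @export
export_candidates <- function(windows, flank_bp = 500000,
                              chrom_lengths = NULL, path = NULL) {
  sig <- windows[windows$significant, , drop = FALSE]
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(sig)) {
    start0 <- pmax(sig$start_bp - 1 - flank_bp, 0)
    end0 <- sig$end_bp + flank_bp
    if (!is.null(chrom_lengths))
      end0 <- pmin(end0, chrom_lengths[as.character(sig$chrom)])
    ord <- order(sig$chrom, start0)
    ch <- as.character(sig$chrom)[ord]; s <- start0[ord]; e <- end0[ord]
    for (i in seq_along(s)) {
      nr <- nrow(out)
      if (nr > 0 && out$chrom[nr] == ch[i] && s[i] <= out$end[nr]) {
        out$end[nr] <- max(out$end[nr], e[i])
      } else {
        out <- rbind(out, data.frame(chrom = ch[i], start = s[i], end = e[i],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(path)) {
    lines <- if (nrow(out))
      paste(out$chrom, format(out$start, scientific = FALSE, trim = TRUE),
            format(out$end, scientific = FALSE, trim = TRUE), sep = "\t")
    else character()
    writeLines(lines, path)
  }
  out
}

#' Convenience driver: five statistics to calibrated DCMS windows
#'
#' Runs the within-population composite for one population: rank-transforms
#' each statistic with its conventional tail (right for iHS, H12 and pi;
#' left for ZHp and Tajima's D), aggregates to the common grid, scores and
#' calibrates.
#'
#' @param ihs site table from [ihs_scan()] (may be NULL to skip)
#' @param h12 window table from [h12_scan()]
#' @param zhp window table from [zhp_scan()]
#' @param freq window table from [window_frequency_stats()]
#' @param grid_bp DCMS grid size (default 500 kb)
#' @param fdr_q FDR threshold
#' @param tails named character vector of tail directions per statistic
#' @param smooth_ihs median-smooth the per-site |iHS| series (width 3)
#'   before aggregation
#' @param min_components minimum statistics per scored window
#' @return calibrated `dcms_windows` table (see [significance_call()])
#' @export
dcms_pipeline <- function(ihs = NULL, h12 = NULL, zhp = NULL, freq = NULL,
                          grid_bp = 500000, fdr_q = 0.05,
                          tails = c(ihs = "right", h12 = "right",
                                    zhp = "left", pi = "right",
                                    tajima_d = "left"),
                          smooth_ihs = TRUE, min_components = 3L) {
  stats_list <- list()
  if (!is.null(ihs) && nrow(ihs)) {
    val <- abs(ihs$std_ihs)
    if (smooth_ihs) {
      for (ch in unique(ihs$chrom)) {
        k <- which(ihs$chrom == ch)
        val[k] <- median_smooth(val[k], 3L)
      }
    }
    stats_list$ihs <- data.frame(chrom = ihs$chrom, pos_bp = ihs$pos_bp,
                                 value = val)
  }
  if (!is.null(h12) && nrow(h12))
    stats_list$h12 <- h12[, c("chrom", "start_bp", "end_bp", "value")]
  if (!is.null(zhp) && nrow(zhp))
    stats_list$zhp <- zhp[, c("chrom", "start_bp", "end_bp", "value")]
  if (!is.null(freq) && nrow(freq)) {
    stats_list$pi <- data.frame(chrom = freq$chrom, start_bp = freq$start_bp,
                                end_bp = freq$end_bp, value = freq$pi)
    stats_list$tajima_d <- data.frame(chrom = freq$chrom,
                                      start_bp = freq$start_bp,
                                      end_bp = freq$end_bp,
                                      value = freq$tajima_d)
  }
  if (!length(stats_list)) stop("no statistics supplied")
  grid <- aggregate_to_grid(stats_list, grid_bp)
  for (nm in names(stats_list))
    if (nm %in% names(grid))
      grid[[nm]] <- rank_to_p(grid[[nm]], tail = tails[[nm]])
  scored <- dcms_scores(grid, min_components = min_components)
  significance_call(scored, fdr_q = fdr_q)
}
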