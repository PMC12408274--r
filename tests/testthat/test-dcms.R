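test_that("running-median smoothing removes spikes and matches a windowed
           oracle", {
  expect_identical(median_smooth(c(3, 1, 4), 1L), c(3, 1, 4))
  expect_equal(median_smooth(c(0, 0, 100, 0, 0), 3L), rep(0, 5))
  withr::local_seed(81)
  x <- rnorm(50)
  for (w in c(3L, 5L)) {
    half <- (w - 1L) / 2L
    ora <- vapply(seq_along(x), function(i)
      median(x[max(1, i - half):min(length(x), i + half)]), 0)
    expect_equal(median_smooth(x, w), ora)
  }
  expect_error(median_smooth(1:5, 4L))
})

test_that("grid aggregation assigns midpoints half-open and averages like
           brute force", {
  site <- data.frame(chrom = "1", pos_bp = c(250000, 500000),
                     value = c(1, 2))
  grid <- aggregate_to_grid(list(s = site), grid_bp = 500000)
  expect_equal(grid$start_bp, c(1, 500001))
  expect_equal(grid$s, c(1, 2))
  win <- data.frame(chrom = "1", start_bp = c(400001, 700001),
                    end_bp = c(600000, 900000), value = c(10, 20))
  grid2 <- aggregate_to_grid(list(w = win), grid_bp = 500000)
  # midpoints 500000 (0-based half-open -> second window) and 800000
  expect_equal(grid2$start_bp, 500001)
  expect_equal(grid2$w, 15)
  withr::local_seed(82)
  rnd <- data.frame(chrom = sample(c("1", "2"), 200, TRUE),
                    pos_bp = sample(1:3e6, 200), value = rnorm(200))
  grid3 <- aggregate_to_grid(list(r = rnd), grid_bp = 500000)
  for (k in seq_len(nrow(grid3))) {
    inwin <- rnd$chrom == grid3$chrom[k] &
      floor(rnd$pos_bp / 5e5) == (grid3$start_bp[k] - 1) / 5e5
    expect_equal(grid3$r[k], mean(rnd$value[inwin]))
  }
})

test_that("rank p-values follow their tail definitions, stay inside (0,1)
           and share ranks under ties", {
  v <- c(3.2, 1.1, 5.0, 2.2, 4.1)
  pr <- rank_to_p(v, "right")
  expect_equal(pr[v == 5.0], 1 / 6)
  expect_equal(pr[v == 1.1], 5 / 6)
  pl <- rank_to_p(v, "left")
  expect_equal(pl[v == 1.1], 1 / 6)
  expect_true(all(pr > 0 & pr < 1))
  tied <- rank_to_p(c(1, 1, 2), "right")
  expect_equal(tied[1], tied[2])
  expect_equal(tied, c((3 - 1.5 + 1) / 4, (3 - 1.5 + 1) / 4, 1 / 4))
  expect_equal(rank_to_p(c(7, 7, 7, 7), "right"), rep(0.5, 4))
  expect_error(rank_to_p(2), "at least 2")
})

test_that("DCMS reproduces closed forms: single statistic and perfectly
           correlated stack", {
  withr::local_seed(83)
  p1 <- runif(30, 0.05, 0.95)
  p1[1] <- 0.1; p1[2] <- 0.5
  tab1 <- data.frame(chrom = "1", start_bp = seq(1, by = 5e5,
                                                 length.out = 30),
                     end_bp = seq(5e5, by = 5e5, length.out = 30), s1 = p1)
  d1 <- dcms_scores(tab1, min_components = 1)
  expect_equal(d1$dcms[1], log10(0.9 / 0.1))
  expect_equal(d1$dcms[2], 0)
  # five identical series: each weight 1/5, composite equals the single one
  tab5 <- tab1
  for (nm in c("s2", "s3", "s4", "s5")) tab5[[nm]] <- p1
  d5 <- dcms_scores(tab5, min_components = 3)
  expect_equal(attr(d5, "weights"), setNames(rep(0.2, 5),
                                             paste0("s", 1:5)))
  expect_equal(d5$dcms, d1$dcms)
})

test_that("independent series raise the weight total and weights match a
           direct correlation computation", {
  withr::local_seed(84)
  n <- 400
  P <- data.frame(chrom = "1",
                  start_bp = seq(1, by = 5e5, length.out = n),
                  end_bp = seq(5e5, by = 5e5, length.out = n),
                  a = runif(n), b = runif(n), c = runif(n))
  d <- dcms_scores(P, min_components = 3)
  w <- attr(d, "weights")
  expect_gt(sum(w), 1)
  R <- cor(as.matrix(P[, c("a", "b", "c")]))
  expect_equal(unname(w), unname(1 / rowSums(abs(R))), tolerance = 1e-12)
  # monotone decreasing in every component p
  P2 <- P; P2$a[1] <- 0.01; P3 <- P; P3$a[1] <- 0.99
  expect_gt(dcms_scores(P2, 3)$dcms[1], dcms_scores(P3, 3)$dcms[1])
})

test_that("windows lacking components are excluded and weights renormalise
           over the available subset", {
  withr::local_seed(85)
  n <- 40
  P <- data.frame(chrom = "1", start_bp = seq(1, by = 5e5, length.out = n),
                  end_bp = seq(5e5, by = 5e5, length.out = n),
                  a = runif(n), b = runif(n), c = runif(n), d = runif(n))
  P$d[1] <- NA; P$c[2] <- NA; P$b[2] <- NA
  d3 <- dcms_scores(P, min_components = 3)
  expect_equal(nrow(d3), n - 1)              # window 2 has only 2 of 4
  w <- attr(d3, "weights")
  l10 <- function(p) log10((1 - p) / p)
  avail <- c("a", "b", "c")
  wj <- w[avail] * sum(w) / sum(w[avail])
  expect_equal(d3$dcms[1],
               sum(wj * vapply(avail, function(s) l10(P[[s]][1]), 0)))
  expect_error(dcms_scores(P[1:5, ], min_components = 3), "fewer than 10")
})

test_that("Gaussian calibration and BH agree with a hand-computed step-up", {
  withr::local_seed(86)
  n <- 25
  tab <- data.frame(chrom = "1", start_bp = seq(1, by = 5e5, length.out = n),
                    end_bp = seq(5e5, by = 5e5, length.out = n),
                    a = runif(n), b = runif(n), c = runif(n))
  d <- significance_call(dcms_scores(tab, 3))
  expect_equal(d$q, oracle_bh(d$p_normal), tolerance = 1e-12)
  # a window sitting exactly at the sample mean has p_normal = 0.5
  dm <- d
  dm$dcms <- c(5, -5, rep(0, n - 2))
  dm <- significance_call(dm)
  expect_equal(dm$p_normal[3], 0.5)
  expect_equal(stats::p.adjust(c(.01, .02, .03, .04, .05), "BH"),
               oracle_bh(c(.01, .02, .03, .04, .05)))
  expect_equal(oracle_bh(c(.01, .02, .03, .04, .05)), rep(0.05, 5))
  dd <- d; dd$dcms <- rep(1, n)
  expect_error(significance_call(dd), "zero variance")
})

test_that("the null pipeline keeps the significant fraction at or below the
           nominal FDR", {
  withr::local_seed(87)
  fracs <- vapply(1:200, function(i) {
    n <- 60
    tab <- data.frame(chrom = "1",
                      start_bp = seq(1, by = 5e5, length.out = n),
                      end_bp = seq(5e5, by = 5e5, length.out = n),
                      a = runif(n), b = runif(n), c = runif(n))
    mean(significance_call(dcms_scores(tab, 3))$significant)
  }, 0)
  expect_lte(mean(fracs), 0.05 + 2 * sd(fracs) / sqrt(length(fracs)) + 0.01)
})

test_that("candidate BED export converts coordinates, merges neighbours and
           handles the empty case", {
  win <- data.frame(chrom = "1", start_bp = c(1000001, 1500001, 4000001),
                    end_bp = c(1500000, 2000000, 4500000),
                    dcms = c(3, 3, 3), p_normal = 0.001, q = 0.01,
                    significant = c(TRUE, TRUE, TRUE))
  bed <- export_candidates(win, flank_bp = 500000)
  expect_equal(nrow(bed), 2)                  # adjacent windows merge
  expect_equal(bed$start[1], 500000)
  expect_equal(bed$end[1], 2500000)
  expect_equal(bed$start[2], 3500000)
  one <- export_candidates(win[1, ], flank_bp = 500000)
  expect_equal(unlist(one[, 2:3], use.names = FALSE), c(500000, 2000000))
  none <- win; none$significant <- FALSE
  path <- withr::local_tempfile(fileext = ".bed")
  out <- export_candidates(none, path = path)
  expect_equal(nrow(out), 0)
  expect_identical(readLines(path), character(0))
  # flank clipping at chromosome bounds
  clip <- export_candidates(win[1, ], flank_bp = 2e6,
                            chrom_lengths = c("1" = 3e6))
  expect_equal(unlist(clip[, 2:3], use.names = FALSE), c(0, 3e6))
})
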