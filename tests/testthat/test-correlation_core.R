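test_that("pearson handles exact linear cases, the longhand formula, and degeneracies", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -2 * x + 3), -1)

  # textbook covariance / (sd_x sd_y) evaluated longhand
  x4 <- c(1, 2, 3, 4)
  y4 <- c(1, 3, 2, 5)
  dx <- x4 - mean(x4)
  dy <- y4 - mean(y4)
  longhand <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  expect_equal(pearson(x4, y4, min_overlap = 4), longhand,
               tolerance = 1e-14)

  expect_true(is.na(pearson(x4, y4)))          # below min_overlap = 10
  expect_true(is.na(pearson(rep(1, 12), 1:12)))  # zero variance
  expect_error(pearson(1:5, 1:4), "length")
  # missing entries restrict to pairwise-complete positions
  xm <- c(x, NA)
  ym <- c(-x, 5)
  expect_equal(pearson(xm, ym), -1)
})

test_that("pairwise correlation enumerates cross pairs, drops degenerate rows, is symmetric", {
  set.seed(11)
  a <- ExpressionMatrix(
    matrix(rnorm(3 * 30), 3, 30,
           dimnames = list(paste0("a", 1:3), paste0("s", 1:30))),
    scale = "log2")
  b <- ExpressionMatrix(
    matrix(rnorm(4 * 30), 4, 30,
           dimnames = list(paste0("b", 1:4), paste0("s", 1:30))),
    scale = "log2")
  pr <- pairwise_correlation(a, b)
  expect_identical(nrow(pr), 12L)
  expect_true(all(abs(pr$rho_xy) <= 1))
  expect_true(all(pr$n_obs == 30L))

  # constant row: its pairs are dropped
  ac <- unclass(a)
  ac[1, ] <- 2
  prc <- pairwise_correlation(ExpressionMatrix(ac, scale = "log2"), b)
  expect_identical(nrow(prc), 8L)
  expect_false(any(prc$x_id == "a1"))

  # symmetry: a x b equals transposed b x a
  pr_t <- pairwise_correlation(b, a)
  key1 <- paste(pr$x_id, pr$y_id)
  key2 <- paste(pr_t$y_id, pr_t$x_id)
  expect_equal(pr$rho_xy[order(key1)], pr_t$rho_xy[order(key2)])

  expect_error(pairwise_correlation(ExpressionMatrix(ac, scale = "raw"), b),
               "log2")
})

test_that("percentile threshold follows the pinned interpolation rule", {
  expect_equal(percentile_threshold(rep(3.5, 20), 0.99), 3.5)
  expect_equal(percentile_threshold(0:100, 0.99), 99)
  expect_equal(percentile_threshold(1:10, 0.99), 9.91)   # 9 + 0.91 * 1
  expect_equal(percentile_threshold(c(1:10, NA, Inf), 0.5),
               interp_quantile(1:10, 0.5))
  expect_error(percentile_threshold(c(NA_real_, Inf)), "no finite")
  # random cross-checks against the independent interpolation oracle
  set.seed(3)
  for (q in c(0.25, 0.5, 0.9, 0.99)) {
    v <- rnorm(137)
    expect_equal(percentile_threshold(v, q), interp_quantile(v, q),
                 tolerance = 1e-12)
  }
})

test_that("pair selection is strict and matches brute-force sort-and-cut", {
  set.seed(4)
  pairs <- data.frame(x_id = paste0("x", 1:100), y_id = paste0("y", 1:100),
                      rho_xy = sample(seq(-0.9, 0.9, length.out = 100)),
                      n_obs = 50L, stringsAsFactors = FALSE)
  sel <- select_pairs(pairs, 0.99)
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$x_id, pairs$x_id[which.max(pairs$rho_xy)])

  tied <- pairs
  tied$rho_xy <- 0.5
  expect_identical(nrow(select_pairs(tied, 0.99)), 0L)   # strict >

  # brute force agreement on larger random input, both tails of q
  big <- data.frame(x_id = "x", y_id = "y", rho_xy = rnorm(10000),
                    n_obs = 50L, stringsAsFactors = FALSE)
  for (q in c(0.5, 0.9, 0.99)) {
    expect_identical(which(big$rho_xy %in% select_pairs(big, q)$rho_xy),
                     sort_and_cut(big$rho_xy, q))
  }
  # absolute-correlation mode ranks by |rho|
  pairs_abs <- pairs
  pairs_abs$rho_xy <- runif(100, -1, 1)
  sel_abs <- select_pairs(pairs_abs, 0.99, use_absolute = TRUE)
  expect_identical(sel_abs$x_id,
                   pairs_abs$x_id[which.max(abs(pairs_abs$rho_xy))])
})

test_that("partial correlation obeys the limiting regimes and the residual oracle", {
  expect_equal(partial_correlation(0.8, 0, 0), 0.8)   # Z uncorrelated
  expect_equal(partial_correlation(0.35, 0.7, 0.5), 0)  # rho_xy = xz * yz
  expect_true(is.na(partial_correlation(0.5, 1, 0.2)))  # degenerate
  expect_error(partial_correlation(1.5, 0, 0), "outside")

  set.seed(5)
  for (i in 1:100) {
    z <- rnorm(30)
    x <- 0.6 * z + rnorm(30)
    y <- -0.4 * z + rnorm(30)
    got <- partial_correlation(cor(x, y), cor(x, z), cor(y, z))
    expect_equal(got, residual_partial_cor(x, y, z), tolerance = 1e-10)
  }
})

test_that("sensitivity correlation is the plain difference, sign included", {
  expect_equal(sensitivity_correlation(0.7, 0.7), 0)
  expect_equal(sensitivity_correlation(0.8, 0), 0.8)
  expect_equal(sensitivity_correlation(0.5, 0.7), -0.2)
})

test_that("triplet scoring covers every pair x miRNA and flags degeneracies", {
  set.seed(6)
  n <- 50L
  samples <- paste0("s", 1:n)
  z1 <- rnorm(n)
  R <- rbind(x1 = -z1 + rnorm(n, sd = 0.2), y1 = -z1 + rnorm(n, sd = 0.2),
             x2 = rnorm(n), y2 = rnorm(n), x3 = rnorm(n))
  colnames(R) <- samples
  Z <- rbind(m1 = z1, m2 = rnorm(n), m3 = R["x1", ])  # m3 collinear with x1
  colnames(Z) <- samples
  rna <- ExpressionMatrix(R, scale = "log2")
  mir <- ExpressionMatrix(Z, scale = "log2")
  pairs <- data.frame(x_id = c("x1", "x2", "x3", "x1", "x2"),
                      y_id = c("y1", "y2", "y1", "y2", "y1"),
                      rho_xy = c(cor(R["x1", ], R["y1", ]),
                                 cor(R["x2", ], R["y2", ]),
                                 cor(R["x3", ], R["y1", ]),
                                 cor(R["x1", ], R["y2", ]),
                                 cor(R["x2", ], R["y1", ])),
                      n_obs = n, stringsAsFactors = FALSE)
  tr <- score_triplets(pairs, mir, rna)
  expect_identical(nrow(tr), 15L)                 # 5 pairs x 3 miRNAs
  # collinear miRNA: degenerate denominator -> missing sensitivity
  deg <- tr[tr$x_id == "x1" & tr$y_id == "y1" & tr$z_id == "m3", ]
  expect_true(is.na(deg$sensitivity))
  # mediated triplet has high S; invariant S = rho_xy - rho_xy|z
  med <- tr[tr$x_id == "x1" & tr$y_id == "y1" & tr$z_id == "m1", ]
  expect_gt(med$sensitivity, 0.5)
  fin <- tr[is.finite(tr$rho_xy_given_z), ]
  expect_equal(fin$sensitivity, fin$rho_xy - fin$rho_xy_given_z)

  # budget guard: warn above warn_at, error above budget
  expect_warning(score_triplets(pairs, mir, rna, warn_at = 10),
                 "triplets")
  expect_error(score_triplets(pairs, mir, rna, budget = 10),
               "exceed the budget")
})

test_that("scored correlations under missing data use a common sample set per triplet", {
  set.seed(61)
  n <- 60L
  samples <- paste0("s", 1:n)
  R <- rbind(x = rnorm(n), y = rnorm(n))
  Z <- rbind(m = rnorm(n))
  R[1, 1:5] <- NA
  Z[1, 4:10] <- NA
  colnames(R) <- samples
  colnames(Z) <- samples
  pairs <- data.frame(x_id = "x", y_id = "y",
                      rho_xy = cor(R[1, ], R[2, ], use = "pairwise"),
                      n_obs = 55L, stringsAsFactors = FALSE)
  tr <- score_triplets(pairs, ExpressionMatrix(Z, scale = "log2"),
                       ExpressionMatrix(R, scale = "log2"))
  common <- !is.na(R[1, ]) & !is.na(R[2, ]) & !is.na(Z[1, ])
  expect_identical(tr$n_obs, as.integer(sum(common)))
  expect_equal(tr$rho_xy, cor(R[1, common], R[2, common]))
  expect_equal(tr$rho_xz, cor(R[1, common], Z[1, common]))
  expect_equal(tr$rho_yz, cor(R[2, common], Z[1, common]))
  expect_equal(tr$rho_xy_given_z,
               residual_partial_cor(R[1, common], R[2, common],
                                    Z[1, common]),
               tolerance = 1e-10)
})

test_that("triplet selection thresholds the pooled finite S distribution strictly", {
  set.seed(8)
  s_vals <- sample(seq(-0.5, 1, length.out = 1000))
  tr <- make_triplets(paste0("x", 1:1000), paste0("y", 1:1000),
                      paste0("z", 1 + (1:1000) %% 7), s = s_vals)
  sel <- select_triplets(tr, 0.99)
  expect_identical(nrow(sel), length(sort_and_cut(s_vals, 0.99)))
  expect_setequal(sel$sensitivity, s_vals[sort_and_cut(s_vals, 0.99)])

  tied <- make_triplets("a", "b", paste0("z", 1:10), s = rep(0.3, 10))
  expect_identical(nrow(select_triplets(tied, 0.99)), 0L)

  med <- select_triplets(tr, 0.5)
  expect_identical(nrow(med), sum(s_vals > interp_quantile(s_vals, 0.5)))

  # NA sensitivities are excluded from the distribution and the output
  tr$sensitivity[1:100] <- NA
  sel_na <- select_triplets(tr, 0.99)
  expect_false(anyNA(sel_na$sensitivity))

  # negative-miRNA-correlation mode restricts eligibility
  tr2 <- make_triplets(paste0("x", 1:10), paste0("y", 1:10),
                       "z1", s = seq(0.1, 1, 0.1))
  tr2$rho_xz <- c(rep(0.4, 5), rep(-0.4, 5))
  sel_neg <- select_triplets(tr2, 0.5, require_negative_mirna_corr = TRUE)
  expect_true(all(sel_neg$rho_xz < 0))
})

test_that("sensitivity matrix chunking follows the 5000-row rule and concatenates exactly", {
  set.seed(9)
  sm <- matrix(rnorm(12000 * 4), 12000, 4,
               dimnames = list(paste0("gA_", 1:12000, "|gB"),
                               paste0("miR_", 1:4)))
  sm[2, 3] <- NA
  d <- withr::local_tempdir()
  paths <- chunk_sensitivity(sm, 5000L, d)
  expect_length(paths, 3L)
  counts <- vapply(paths, function(p) nrow(utils::read.delim(p)),
                   integer(1L))
  expect_identical(unname(counts), c(5000L, 5000L, 2000L))
  back <- read_sensitivity_blocks(paths)
  expect_identical(dimnames(back), dimnames(sm))
  expect_equal(back, sm)

  one <- chunk_sensitivity(sm[1:100, , drop = FALSE], 5000L, d,
                           prefix = "small")
  expect_length(one, 1L)
})
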