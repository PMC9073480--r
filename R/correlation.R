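#' Pearson correlation over pairwise-complete observations
#'
#' Correlation of two expression profiles using only positions where both
#' values are present. Returns `NA` when fewer than `min_overlap` complete
#' positions remain or when either profile is constant on them.
#'
#' @param x,y numeric vectors of equal length; `NA` allowed.
#' @param min_overlap minimum number of complete positions.
#' @return a single numeric value or `NA`.
#' @export
pearson <- function(x, y, min_overlap = 10L) {
  if (length(x) != length(y)) {
    sn_stop("pearson: vectors differ in length (%d vs %d)",
            length(x), length(y))
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_overlap) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' All cross-class Pearson correlations
#'
#' One record per (row of `a`) x (row of `b`) pair with a finite
#' pairwise-complete correlation; pairs whose correlation is undefined
#' (too few shared samples, zero variance) are dropped with a logged count.
#'
#' @param a,b [ExpressionMatrix] objects on the log2 scale with identical
#'   sample ordering (see [align_samples()]).
#' @param min_overlap minimum pairwise-complete sample count per pair.
#' @return data.frame with columns `x_id`, `y_id`, `rho_xy`, `n_obs`.
#' @export
pairwise_correlation <- function(a, b, min_overlap = 10L) {
  stopifnot(inherits(a, "ExpressionMatrix"), inherits(b, "ExpressionMatrix"))
  if (attr(a, "scale") != "log2" || attr(b, "scale") != "log2") {
    sn_stop("pairwise_correlation expects log2-scaled matrices")
  }
  if (!identical(colnames(a), colnames(b))) {
    sn_stop("sample sets/order differ between matrices; run align_samples()")
  }
  va <- unclass(a)
  vb <- unclass(b)
  r <- suppressWarnings(stats::cor(t(va), t(vb),
                                   use = "pairwise.complete.obs"))
  n_obs <- (!is.na(va)) %*% t(!is.na(vb))
  r[n_obs < min_overlap] <- NA_real_
  df <- data.frame(
    x_id = rep(rownames(va), times = nrow(vb)),
    y_id = rep(rownames(vb), each = nrow(va)),
    rho_xy = as.vector(r),
    n_obs = as.vector(n_obs),
    stringsAsFactors = FALSE
  )
  bad <- is.na(df$rho_xy)
  if (any(bad)) {
    sn_log("pairwise_correlation: dropped %d of %d pairs with undefined r",
           sum(bad), nrow(df))
  }
  df[!bad, , drop = FALSE]
}

#' Percentile threshold by linear interpolation
#'
#' The q-quantile computed by linear interpolation between order
#' statistics: on sorted values `v[1] <= ... <= v[n]`, with
#' `h = q * (n - 1)` (0-based), the threshold is
#' `v[floor(h)+1] + (h - floor(h)) * (v[floor(h)+2] - v[floor(h)+1])`.
#' This is `stats::quantile()` type 7, pinned here so that thresholds are
#' reproducible across implementations. Missing values are excluded.
#'
#' @param values numeric vector with at least one finite value.
#' @param q quantile in (0, 1); default the 99th percentile.
#' @return the threshold value.
#' @export
percentile_threshold <- function(values, q = 0.99) {
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1)
  v <- values[is.finite(values)]
  if (length(v) == 0L) sn_stop("percentile_threshold: no finite values")
  unname(stats::quantile(v, probs = q, type = 7, names = FALSE))
}

#' Select highly correlated RNA pairs
#'
#' Keeps the pairs whose correlation is strictly greater than the
#' `q`-percentile of the overall correlation distribution. By default the
#' signed correlation is used (ceRNA crosstalk predicts positive
#' co-expression); `use_absolute = TRUE` thresholds `|rho|` instead.
#'
#' @param pairs data.frame from [pairwise_correlation()].
#' @param q percentile in (0, 1); default 0.99.
#' @param use_absolute threshold the absolute correlation.
#' @return the surviving subset of `pairs`; the threshold is logged and
#'   attached as attribute `threshold`.
#' @export
select_pairs <- function(pairs, q = 0.99, use_absolute = FALSE) {
  if (!nrow(pairs)) sn_stop("select_pairs: empty pair list")
  score <- if (use_absolute) abs(pairs$rho_xy) else pairs$rho_xy
  thr <- percentile_threshold(score, q)
  keep <- !is.na(score) & score > thr
  sn_log("select_pairs: %d of %d pairs above the %.4g threshold (q = %g)",
         sum(keep), nrow(pairs), thr, q)
  out <- pairs[keep, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Partial correlation from three pairwise correlations
#'
#' Correlation of X and Y after removing the linear effect of Z:
#' `(rho_xy - rho_xz * rho_yz) / (sqrt(1 - rho_xz^2) * sqrt(1 - rho_yz^2))`.
#' When Z is (nearly) perfectly correlated with X or Y the denominator
#' vanishes and the result is `NA` rather than infinite, which keeps the
#' downstream sensitivity distribution finite. Vectorized.
#'
#' @param rho_xy,rho_xz,rho_yz correlations in `[-1, 1]`; `NA` propagates.
#' @param eps degeneracy guard: `NA` when `1 - rho^2 <= eps` for either
#'   controlling correlation.
#' @return numeric vector of partial correlations (`NA` where undefined).
#' @export
partial_correlation <- function(rho_xy, rho_xz, rho_yz, eps = 1e-12) {
  chk <- c(rho_xy, rho_xz, rho_yz)
  if (any(abs(chk) > 1 + 1e-8, na.rm = TRUE)) {
    sn_stop("partial_correlation: correlation outside [-1, 1]")
  }
  d2x <- 1 - rho_xz^2
  d2y <- 1 - rho_yz^2
  out <- (rho_xy - rho_xz * rho_yz) / (sqrt(pmax(d2x, 0)) *
                                         sqrt(pmax(d2y, 0)))
  out[!is.na(d2x) & d2x <= eps] <- NA_real_
  out[!is.na(d2y) & d2y <= eps] <- NA_real_
  out
}

#' Sensitivity correlation
#'
#' The drop from the Pearson correlation of an RNA pair to their partial
#' correlation controlling for a miRNA: `S = rho_xy - rho_xy_given_z`.
#' `S ~ 0` means the co-expression is direct (the miRNA explains nothing);
#' `S` near `rho_xy` means the miRNA mediates it (partial correlation near
#' zero). Negative values are permitted; no clamping. Vectorized.
#'
#' @param rho_xy,rho_xy_given_z numeric vectors; `NA` propagates.
#' @return `rho_xy - rho_xy_given_z`.
#' @export
sensitivity_correlation <- function(rho_xy, rho_xy_given_z) {
  rho_xy - rho_xy_given_z
}
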