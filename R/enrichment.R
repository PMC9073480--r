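#' Hypergeometric upper-tail probability
#'
#' For a universe of `u` RNA pairs of which `k` share the binding site
#' for a miRNA (the property) and `s` were selected as high-sensitivity
#' for it, the probability of observing `x` or more pairs that are both
#' selected and site-sharing:
#' `p = sum_{i=x}^{s} C(k, i) C(u - k, s - i) / C(u, s)`.
#' Evaluated through the hypergeometric survival function (no `1 - CDF`
#' subtraction on this side), so it is exact at `x = 0` (`p = 1`) and
#' stable in the far tail. Vectorized.
#'
#' @param u universe size (number of top-correlated RNA pairs).
#' @param k pairs sharing the miRNA's binding site, `k <= u`.
#' @param s selected high-sensitivity pairs, `s <= u`.
#' @param x overlap, `0 <= x <= min(k, s)`.
#' @return upper-tail p-value(s) in `[0, 1]`.
#' @export
hypergeometric_upper_tail <- function(u, k, s, x) {
  n <- max(length(u), length(k), length(s), length(x))
  u <- rep_len(as.integer(u), n)
  k <- rep_len(as.integer(k), n)
  s <- rep_len(as.integer(s), n)
  x <- rep_len(as.integer(x), n)
  if (any(u < 0)) sn_stop("violated: u >= 0")
  if (any(k > u)) sn_stop("violated: k <= u")
  if (any(s > u)) sn_stop("violated: s <= u")
  if (any(x < 0)) sn_stop("violated: x >= 0")
  if (any(x > pmin(k, s))) sn_stop("violated: x <= min(k, s)")
  # P[X >= x] for X ~ Hypergeometric(k white, u-k black, s drawn)
  stats::phyper(x - 1L, m = k, n = u - k, k = s, lower.tail = FALSE)
}

#' Per-miRNA seed-match enrichment
#'
#' For each miRNA Z the test asks whether the RNA pairs selected as
#' high-sensitivity for Z are enriched in pairs whose two members both
#' carry a binding site for Z. Counts over the universe of distinct
#' top-correlated pairs:
#' \describe{
#'   \item{U}{distinct scored (top-correlated) pairs;}
#'   \item{K}{pairs with both partners targets of Z;}
#'   \item{S}{pairs appearing in a selected triplet with Z;}
#'   \item{X}{pairs counted in both K and S.}
#' }
#' Raw p-values come from [hypergeometric_upper_tail()]; BH-adjusted
#' q-values are added across all tested miRNAs. No p-value filtering is
#' applied here: p is reported as downstream edge information.
#'
#' @param triplets_all all scored triplets ([score_triplets()] output).
#' @param triplets_selected the selected subset ([select_triplets()]).
#' @param tm a [TargetMap].
#' @return data.frame with columns `z_id`, `universe_u`, `property_k`,
#'   `selection_s`, `overlap_x`, `p_value`, `q_value`, ordered by
#'   increasing p.
#' @export
enrich_all <- function(triplets_all, triplets_selected, tm) {
  stopifnot(inherits(tm, "TargetMap"))
  if (!nrow(triplets_all)) sn_stop("enrich_all: no scored triplets")
  updf <- unique(triplets_all[, c("x_id", "y_id")])
  u <- nrow(updf)
  px <- updf$x_id
  py <- updf$y_id
  pair_all <- paste(px, py, sep = "\r")
  sel_key <- paste(triplets_selected$z_id, triplets_selected$x_id,
                   triplets_selected$y_id, sep = "\r")
  mirnas <- unique(triplets_all$z_id)
  rec <- lapply(mirnas, function(z) {
    shares <- has_target(tm, z, px) & has_target(tm, z, py)
    sel <- paste(z, px, py, sep = "\r") %in% sel_key
    data.frame(z_id = z, universe_u = u, property_k = sum(shares),
               selection_s = sum(sel), overlap_x = sum(shares & sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  out$p_value <- hypergeometric_upper_tail(out$universe_u, out$property_k,
                                           out$selection_s, out$overlap_x)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$z_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
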