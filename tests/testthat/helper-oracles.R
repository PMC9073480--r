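# Independent oracles used to cross-check the implementation. Each one is
# deliberately written from first principles (no calls into the package's
# computational path, no shared helpers).

options(spongenet.quiet = TRUE)

# partial correlation as the Pearson correlation of least-squares
# residuals of X on Z and Y on Z
residual_partial_cor <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# hypergeometric upper tail by direct evaluation of the combinatorial sum
hyper_upper_sum <- function(u, k, s, x) {
  if (x > min(k, s)) return(0)
  i <- x:min(k, s)
  sum(choose(k, i) * choose(u - k, s - i)) / choose(u, s)
}

# hypergeometric upper tail by exhaustive enumeration of all C(u, s)
# selections from a universe in which k items carry the property
hyper_upper_enum <- function(u, k, s, x) {
  if (s == 0L) return(as.numeric(x == 0L))
  sel <- utils::combn(u, s)
  hits <- colSums(sel <= k)            # items 1..k carry the property
  mean(hits >= x)
}

# naive all-windows seed scan: 0-based offsets of exact site occurrences
naive_site_scan <- function(site, target) {
  w <- nchar(site)
  hits <- integer(0)
  if (nchar(target) < w) return(hits)
  for (p in seq_len(nchar(target) - w + 1L)) {
    if (substr(target, p, p + w - 1L) == site) hits <- c(hits, p - 1L)
  }
  hits
}

# connected components by union-find on an edge list
union_find_components <- function(nodes, from, to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(a) {
    while (parent[[a]] != a) {
      parent[[a]] <<- parent[[parent[[a]]]]
      a <- parent[[a]]
    }
    a
  }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1L))
  unname(split(nodes, roots))
}

# quantile by the pinned interpolation rule, written independently
interp_quantile <- function(v, q) {
  v <- sort(v[is.finite(v)])
  h <- q * (length(v) - 1)
  lo <- floor(h)
  if (lo + 2L > length(v)) return(v[length(v)])
  v[lo + 1L] + (h - lo) * (v[lo + 2L] - v[lo + 1L])
}

# brute-force "sort and cut": records strictly above the q-quantile
sort_and_cut <- function(values, q) {
  which(values > interp_quantile(values, q))
}

# small deterministic expression fixture: planted correlated pair plus
# independent background, written on the raw scale
tiny_expression <- function(n_genes = 6L, n_samples = 40L, seed = 7L) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n_genes * n_samples, mean = 6), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  ExpressionMatrix(2^v, scale = "raw")
}

# minimal triplet table for enrichment / network tests
make_triplets <- function(x, y, z, s, rho = 0.9, seed_match = NA) {
  data.frame(x_id = x, y_id = y, z_id = z, rho_xy = rho,
             rho_xz = -0.5, rho_yz = -0.5, rho_xy_given_z = rho - s,
             sensitivity = s, n_obs = 100L, seed_match = seed_match,
             stringsAsFactors = FALSE)
}
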