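#' Score all (RNA pair, miRNA) triplets
#'
#' For every selected RNA pair (X, Y) and every miRNA Z, computes the
#' three Pearson correlations, the partial correlation of X and Y given
#' Z, and the sensitivity correlation `S = rho_xy - rho_xy|z`. The three
#' correlations entering one partial correlation are computed on a common
#' sample set (positions complete in X, Y and Z), so the formula is
#' internally consistent under missing data.
#'
#' Triplets whose partial correlation is undefined (miRNA nearly
#' collinear with either RNA, or too few shared samples) carry a missing
#' sensitivity; they are counted and excluded from later thresholding but
#' kept in the output, so that the output always has exactly
#' `nrow(pairs) * nrow(mirna)` rows.
#'
#' @param pairs selected pairs from [select_pairs()] (columns `x_id`,
#'   `y_id`, `rho_xy`).
#' @param mirna miRNA [ExpressionMatrix], log2 scale, samples aligned
#'   with `rna`.
#' @param rna RNA [ExpressionMatrix] containing all `x_id`/`y_id` rows.
#' @param min_overlap minimum triple-complete sample count.
#' @param budget hard cap on `nrow(pairs) * nrow(mirna)`; exceeding it is
#'   an error. A warning is emitted above `warn_at` (the practical
#'   complexity guideline of about 1e6 triplets).
#' @param warn_at soft warning threshold on the triplet count.
#' @return data.frame with columns `x_id`, `y_id`, `z_id`, `rho_xy`,
#'   `rho_xz`, `rho_yz`, `rho_xy_given_z`, `sensitivity`, `n_obs`,
#'   `seed_match` (initialized `NA`, see [annotate_seed_match()]).
#' @export
score_triplets <- function(pairs, mirna, rna, min_overlap = 10L,
                           budget = 1e7, warn_at = 1e6) {
  stopifnot(inherits(mirna, "ExpressionMatrix"),
            inherits(rna, "ExpressionMatrix"))
  if (!nrow(pairs)) sn_stop("score_triplets: empty pair list")
  if (!identical(colnames(mirna), colnames(rna))) {
    sn_stop("sample sets/order differ between RNA and miRNA matrices")
  }
  missing_rows <- setdiff(unique(c(pairs$x_id, pairs$y_id)), rownames(rna))
  if (length(missing_rows)) {
    sn_stop("pair member(s) absent from RNA matrix: %s",
            paste(utils::head(missing_rows, 5L), collapse = ", "))
  }
  n_trip <- as.double(nrow(pairs)) * nrow(mirna)
  if (n_trip > budget) {
    sn_stop("%.0f candidate triplets exceed the budget of %.0f", n_trip,
            budget)
  }
  if (n_trip > warn_at) {
    warning(sprintf("%.0f candidate triplets; runs beyond ~1e6 get expensive",
                    n_trip), call. = FALSE)
  }

  Z <- unclass(mirna)
  R <- unclass(rna)
  zna <- is.na(Z)
  k <- nrow(Z)
  res <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    x <- R[pairs$x_id[p], ]
    y <- R[pairs$y_id[p], ]
    mask <- !is.na(x) & !is.na(y)
    rho_xy <- rep(NA_real_, k)
    rho_xz <- rep(NA_real_, k)
    rho_yz <- rep(NA_real_, k)
    nob <- integer(k)
    # miRNAs fully observed on the pair's complete positions share the
    # common sample set `mask`; batch them through one cor() call
    clean <- which(rowSums(zna[, mask, drop = FALSE]) == 0L)
    dirty <- setdiff(seq_len(k), clean)
    if (length(clean) && sum(mask) >= min_overlap) {
      xy <- cbind(x[mask], y[mask])
      cz <- suppressWarnings(
        stats::cor(xy, t(Z[clean, mask, drop = FALSE])))
      rho_xz[clean] <- cz[1L, ]
      rho_yz[clean] <- cz[2L, ]
      rho_xy[clean] <- pairs$rho_xy[p]   # same sample set as the pair
      nob[clean] <- sum(mask)
    }
    for (g in dirty) {
      common <- mask & !zna[g, ]
      nob[g] <- sum(common)
      if (nob[g] < min_overlap) next
      cc <- suppressWarnings(
        stats::cor(cbind(x[common], y[common], Z[g, common])))
      rho_xy[g] <- cc[1L, 2L]
      rho_xz[g] <- cc[1L, 3L]
      rho_yz[g] <- cc[2L, 3L]
    }
    pc <- partial_correlation(rho_xy, rho_xz, rho_yz)
    res[[p]] <- data.frame(
      x_id = pairs$x_id[p], y_id = pairs$y_id[p], z_id = rownames(Z),
      rho_xy = rho_xy, rho_xz = rho_xz, rho_yz = rho_yz,
      rho_xy_given_z = pc,
      sensitivity = sensitivity_correlation(rho_xy, pc),
      n_obs = nob, seed_match = NA, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  n_undef <- sum(is.na(out$sensitivity))
  if (n_undef) {
    sn_log("score_triplets: %d of %d triplets have undefined sensitivity",
           n_undef, nrow(out))
  }
  out
}

#' Select high-sensitivity triplets
#'
#' Keeps the triplets with sensitivity strictly greater than the
#' `q`-percentile of the pooled (all-miRNA) finite sensitivity
#' distribution. Optionally restricts the candidates to triplets where
#' the miRNA is negatively correlated with both RNAs (the repression
#' regime); the threshold is then computed on that restricted
#' distribution.
#'
#' @param triplets data.frame from [score_triplets()].
#' @param q percentile in (0, 1); default 0.99.
#' @param require_negative_mirna_corr require `rho_xz < 0` and
#'   `rho_yz < 0`.
#' @return the surviving subset, threshold attached as attribute
#'   `threshold`.
#' @export
select_triplets <- function(triplets, q = 0.99,
                            require_negative_mirna_corr = FALSE) {
  if (!nrow(triplets)) sn_stop("select_triplets: empty triplet list")
  eligible <- is.finite(triplets$sensitivity)
  if (require_negative_mirna_corr) {
    eligible <- eligible & !is.na(triplets$rho_xz) &
      !is.na(triplets$rho_yz) & triplets$rho_xz < 0 & triplets$rho_yz < 0
  }
  if (!any(eligible)) sn_stop("select_triplets: no finite sensitivity values")
  thr <- percentile_threshold(triplets$sensitivity[eligible], q)
  keep <- eligible & triplets$sensitivity > thr
  sn_log("select_triplets: %d of %d triplets above the S threshold %.4g (q = %g)",
         sum(keep), nrow(triplets), thr, q)
  out <- triplets[keep, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Sensitivity matrix (pairs x miRNAs)
#'
#' Reshapes scored triplets into the matrix rendered as the sensitivity
#' heatmap: one row per selected RNA pair, one column per miRNA, cells =
#' sensitivity (NA where undefined). Row and column order follow first
#' appearance in `triplets`.
#'
#' @param triplets data.frame from [score_triplets()].
#' @return numeric matrix with rownames `"<x_id>|<y_id>"` and colnames
#'   the miRNA ids.
#' @export
sensitivity_matrix <- function(triplets) {
  if (!nrow(triplets)) sn_stop("sensitivity_matrix: empty triplet list")
  pair_lab <- paste(triplets$x_id, triplets$y_id, sep = "|")
  rows <- unique(pair_lab)
  cols <- unique(triplets$z_id)
  sm <- matrix(NA_real_, length(rows), length(cols),
               dimnames = list(rows, cols))
  sm[cbind(match(pair_lab, rows), match(triplets$z_id, cols))] <-
    triplets$sensitivity
  sm
}

#' Write the sensitivity matrix in row chunks
#'
#' Very large sensitivity matrices exceed what one heatmap (or one file
#' viewer) handles comfortably, so the matrix is segregated into blocks
#' of at most `max_rows` RNA pairs each. Row/column labels are preserved
#' and concatenating the blocks reproduces the matrix exactly.
#'
#' @param sm matrix from [sensitivity_matrix()].
#' @param max_rows maximum RNA pairs per block (default 5000).
#' @param out_dir output directory (created if absent).
#' @param prefix file-name prefix; blocks are
#'   `<prefix>_block_001.tsv`, ...
#' @return character vector of file paths.
#' @export
chunk_sensitivity <- function(sm, max_rows = 5000L, out_dir,
                              prefix = "sensitivity") {
  stopifnot(is.matrix(sm), nrow(sm) >= 1L, max_rows >= 1L)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) sn_stop("cannot create output directory: %s", out_dir)
  }
  n_blocks <- ceiling(nrow(sm) / max_rows)
  paths <- character(n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- seq.int((b - 1L) * max_rows + 1L, min(b * max_rows, nrow(sm)))
    block <- sm[rows, , drop = FALSE]
    df <- data.frame(pair = rownames(block),
                     format(block, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("pair", colnames(block))
    paths[b] <- file.path(out_dir, sprintf("%s_block_%03d.tsv", prefix, b))
    utils::write.table(df, paths[b], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  sn_log("chunk_sensitivity: wrote %d block(s) for %d pairs x %d miRNAs",
         n_blocks, nrow(sm), ncol(sm))
  paths
}

#' Read back chunked sensitivity blocks
#'
#' Concatenates the TSV blocks written by [chunk_sensitivity()] into one
#' matrix (used for round-trip verification).
#'
#' @param paths files in block order.
#' @return numeric matrix.
#' @export
read_sensitivity_blocks <- function(paths) {
  blocks <- lapply(paths, function(p) {
    df <- utils::read.delim(p, check.names = FALSE, colClasses = "character")
    mm <- as.matrix(df[, -1L, drop = FALSE])
    m <- matrix(as.numeric(mm), nrow = nrow(mm),
                dimnames = list(df[[1L]], colnames(mm)))
    m
  })
  do.call(rbind, blocks)
}
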