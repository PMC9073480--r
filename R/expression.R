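#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric matrix of expression values
#' (rows = genes or miRNAs, columns = samples) carrying a `scale` tag so
#' that downstream correlation code can refuse raw (un-logged) input and
#' the log2 transform can refuse to run twice.
#'
#' @param values numeric matrix with unique, non-empty rownames (feature
#'   identifiers) and colnames (sample identifiers). `NA` marks missing
#'   measurements.
#' @param scale `"raw"` for normalized linear-scale units (e.g. FPKM) or
#'   `"log2"` after transformation.
#' @return an object of class `ExpressionMatrix` (a numeric matrix with a
#'   `scale` attribute).
#' @examples
#' m <- matrix(2^(1:6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- ExpressionMatrix(m, scale = "raw")
#' expr_scale(em)
#' @export
ExpressionMatrix <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    sn_stop("'values' must be a numeric matrix")
  }
  rid <- rownames(values)
  sid <- colnames(values)
  if (is.null(rid) || anyNA(rid) || any(rid == "")) {
    sn_stop("expression matrix needs non-empty row identifiers")
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "")) {
    sn_stop("expression matrix needs non-empty sample identifiers")
  }
  if (anyDuplicated(rid)) {
    sn_stop("duplicate row identifier(s): %s",
            paste(unique(rid[duplicated(rid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    sn_stop("duplicate sample identifier(s): %s",
            paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (ncol(values) == 0L) sn_stop("expression matrix has zero samples")
  structure(values, scale = scale, class = c("ExpressionMatrix", "matrix"))
}

#' @rdname ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @export
expr_scale <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  attr(x, "scale")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s scale], %d missing\n",
              nrow(x), ncol(x), attr(x, "scale"), sum(is.na(x))))
  invisible(x)
}

# rebuild the class/scale attributes after subsetting
.as_expr <- function(values, scale) {
  structure(values, scale = scale, class = c("ExpressionMatrix", "matrix"))
}

#' Read an expression matrix from TSV
#'
#' Expected layout: first column = feature identifier, header row = sample
#' identifiers, remaining cells numeric. Empty cells and the tokens
#' `NA`, `NaN`, `null` (case-insensitive) are read as missing.
#'
#' @param path path to a tab-separated file.
#' @param scale scale tag to stamp on the result; inputs are normally raw
#'   normalized units (e.g. FPKM).
#' @return an [ExpressionMatrix].
#' @export
read_expression <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) sn_stop("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "",
                          na.strings = character(0))
  if (ncol(df) < 2L) sn_stop("no sample columns in %s", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    sn_stop("duplicate row identifier(s) in %s: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cells <- as.matrix(df[, -1L, drop = FALSE])
  is_missing <- is.na(cells) | tolower(trimws(cells)) %in% .NA_TOKENS
  num <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(num) & !is_missing)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
    sn_stop("non-numeric cell '%s' at row '%s', sample '%s' in %s",
            cells[bad[1L]], ids[i], colnames(cells)[j], path)
  }
  num[is_missing] <- NA_real_
  values <- matrix(num, nrow = nrow(cells),
                   dimnames = list(ids, colnames(cells)))
  ExpressionMatrix(values, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: feature ids in the first column
#' (header `id`), one column per sample, `NA` for missing entries.
#' Finite values round-trip bitwise (written with full precision).
#'
#' @param m an [ExpressionMatrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(id = rownames(m),
                   format(unclass(m), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a gene biotype annotation table
#'
#' Two-column TSV mapping `gene_id` to a molecular biotype label such as
#' `protein_coding` or `lncRNA`. An optional header is detected when the
#' second field of the first line matches `biotype` (case-insensitive).
#'
#' @param path path to the TSV.
#' @return named character vector: `names` = gene ids, values = biotypes.
#' @export
read_biotype_annotation <- function(path) {
  if (!file.exists(path)) sn_stop("file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) sn_stop("annotation table needs two columns: %s", path)
  if (nrow(df) && grepl("biotype", df[[2L]][1L], ignore.case = TRUE)) {
    df <- df[-1L, , drop = FALSE]
  }
  if (anyDuplicated(df[[1L]])) {
    dup <- unique(df[[1L]][duplicated(df[[1L]])])
    sn_stop("gene(s) with more than one biotype: %s",
            paste(dup, collapse = ", "))
  }
  stats::setNames(df[[2L]], df[[1L]])
}

#' Split an expression matrix into two candidate-ceRNA classes
#'
#' Separates the features of `m` into the two classes of candidate
#' ceRNAs to be tested against each other (for instance protein-coding
#' mRNAs versus lncRNAs). Features without an annotation, or annotated
#' with a biotype in neither class, are dropped with a logged count.
#'
#' @param m an [ExpressionMatrix].
#' @param ann named biotype vector from [read_biotype_annotation()].
#' @param class_a,class_b character vectors of biotype labels; must be
#'   disjoint and each class must be non-empty after partitioning.
#' @return list with elements `a` and `b`, both [ExpressionMatrix] objects
#'   with disjoint row sets.
#' @export
partition_by_biotype <- function(m, ann, class_a, class_b) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (length(intersect(class_a, class_b))) {
    sn_stop("class_a and class_b share biotype label(s): %s",
            paste(intersect(class_a, class_b), collapse = ", "))
  }
  bt <- ann[rownames(m)]                  # NA for unannotated genes
  in_a <- !is.na(bt) & bt %in% class_a
  in_b <- !is.na(bt) & bt %in% class_b
  dropped <- sum(!(in_a | in_b))
  if (dropped) {
    sn_log("partition_by_biotype: dropped %d feature(s) with no/other biotype",
           dropped)
  }
  if (!any(in_a)) sn_stop("no features in class_a after partition")
  if (!any(in_b)) sn_stop("no features in class_b after partition")
  sc <- attr(m, "scale")
  list(a = .as_expr(unclass(m)[in_a, , drop = FALSE], sc),
       b = .as_expr(unclass(m)[in_b, , drop = FALSE], sc))
}

#' Remove features with too many missing values
#'
#' Drops every row whose fraction of missing samples is strictly greater
#' than `max_missing_fraction` (default: more than 10 percent of samples).
#' Row order is otherwise preserved and the removal count is logged.
#'
#' @param m an [ExpressionMatrix].
#' @param max_missing_fraction maximum tolerated missing fraction in
#'   `[0, 1]`; a row at exactly the threshold is kept.
#' @return the filtered [ExpressionMatrix].
#' @export
filter_missing <- function(m, max_missing_fraction = 0.10) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            is.numeric(max_missing_fraction),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  if (ncol(m) < 1L) sn_stop("matrix has no samples")
  frac <- rowMeans(is.na(unclass(m)))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) {
    sn_stop(paste0("all %d rows exceed the %.0f%% missingness threshold; ",
                   "consider relaxing max_missing_fraction"),
            nrow(m), 100 * max_missing_fraction)
  }
  if (any(!keep)) {
    sn_log("filter_missing: removed %d of %d rows (> %.0f%% missing)",
           sum(!keep), nrow(m), 100 * max_missing_fraction)
  }
  .as_expr(unclass(m)[keep, , drop = FALSE], attr(m, "scale"))
}

#' Log2-transform an expression matrix
#'
#' Applies `log2(v + pseudocount)` to every finite entry. With
#' `pseudocount = 0`, values `<= 0` cannot be logged; under the default
#' policy they become missing (so that a subsequent [filter_missing()]
#' sees them), under `"error"` the first offending coordinate is reported.
#'
#' @param m an [ExpressionMatrix] on the raw scale.
#' @param pseudocount non-negative offset added before the log.
#' @param nonpositive_policy `"to_missing"` or `"error"`.
#' @return the transformed [ExpressionMatrix] with scale `"log2"`.
#' @export
log2_transform <- function(m, pseudocount = 0,
                           nonpositive_policy = c("to_missing", "error")) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            is.numeric(pseudocount), pseudocount >= 0)
  nonpositive_policy <- match.arg(nonpositive_policy)
  if (attr(m, "scale") == "log2") {
    sn_stop("matrix is already log2-scaled (double-transform guard)")
  }
  v <- unclass(m)
  shifted <- v + pseudocount
  bad <- !is.na(shifted) & shifted <= 0
  if (any(bad)) {
    if (nonpositive_policy == "error") {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      sn_stop("non-positive value %.6g at row '%s', sample '%s'",
              v[bad][1L], rownames(v)[idx[1L]], colnames(v)[idx[2L]])
    }
    shifted[bad] <- NA_real_
    sn_log("log2_transform: %d non-positive value(s) set to missing",
           sum(bad))
  }
  .as_expr(log2(shifted), "log2")
}

#' Align two expression matrices on their shared samples
#'
#' Paired-sample analyses require the RNA and miRNA matrices to cover the
#' same samples in the same order; extras on either side are dropped with
#' a logged count.
#'
#' @param rna,mirna [ExpressionMatrix] objects.
#' @return list with elements `rna` and `mirna` restricted to the shared
#'   samples, ordered as in `rna`.
#' @export
align_samples <- function(rna, mirna) {
  stopifnot(inherits(rna, "ExpressionMatrix"),
            inherits(mirna, "ExpressionMatrix"))
  common <- intersect(colnames(rna), colnames(mirna))
  if (length(common) == 0L) sn_stop("no shared samples between matrices")
  d1 <- ncol(rna) - length(common)
  d2 <- ncol(mirna) - length(common)
  if (d1 || d2) {
    sn_log("align_samples: dropped %d RNA-only and %d miRNA-only sample(s); %d shared",
           d1, d2, length(common))
  }
  list(rna = .as_expr(unclass(rna)[, common, drop = FALSE],
                      attr(rna, "scale")),
       mirna = .as_expr(unclass(mirna)[, common, drop = FALSE],
                        attr(mirna, "scale")))
}
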