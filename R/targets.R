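#' miRNA-target interaction map
#'
#' Set of (miRNA, gene) interaction assertions, the local stand-in for
#' TargetScan / miRWalk downloads. Each pair carries a provenance tag:
#' `"table"` when read from a user-supplied file, `"seed_scan"` when
#' produced by de-novo seed scanning ([build_target_map_from_sequences()]).
#' Membership queries are O(1) via an internal hashed environment.
#'
#' @param mirna_id,gene_id character vectors of equal length.
#' @param provenance single tag or vector recycled over the pairs.
#' @return object of class `TargetMap`.
#' @seealso [read_target_table()], [has_target()], [target_map_union()]
#' @export
TargetMap <- function(mirna_id = character(), gene_id = character(),
                      provenance = "table") {
  stopifnot(length(mirna_id) == length(gene_id))
  df <- data.frame(mirna_id = as.character(mirna_id),
                   gene_id = as.character(gene_id),
                   provenance = rep_len(as.character(provenance),
                                        length(mirna_id)),
                   stringsAsFactors = FALSE)
  key <- paste(df$mirna_id, df$gene_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) df <- df[!dup, , drop = FALSE]
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(1L, nrow(df)))
  for (k in key[!dup]) assign(k, TRUE, envir = env)
  structure(list(pairs = df, index = env), class = "TargetMap")
}

#' @export
print.TargetMap <- function(x, ...) {
  cat(sprintf("TargetMap: %d pairs (%d miRNAs, %d genes)\n",
              nrow(x$pairs), length(unique(x$pairs$mirna_id)),
              length(unique(x$pairs$gene_id))))
  invisible(x)
}

#' @rdname TargetMap
#' @param tm a `TargetMap`.
#' @export
target_pairs <- function(tm) {
  stopifnot(inherits(tm, "TargetMap"))
  tm$pairs
}

#' Query target-map membership
#'
#' Vectorized over `mirna_id` / `gene_id` (recycled to equal length).
#'
#' @param tm a [TargetMap].
#' @param mirna_id,gene_id identifiers to query.
#' @return logical vector; `FALSE` for absent pairs.
#' @export
has_target <- function(tm, mirna_id, gene_id) {
  stopifnot(inherits(tm, "TargetMap"))
  n <- max(length(mirna_id), length(gene_id))
  key <- paste(rep_len(as.character(mirna_id), n),
               rep_len(as.character(gene_id), n), sep = "\r")
  vapply(key, exists, logical(1L), envir = tm$index, inherits = FALSE,
         USE.NAMES = FALSE)
}

#' Read a miRNA-target interaction table
#'
#' Two-column TSV `(mirna_id, gene_id)`; an optional header line is
#' detected when the first field matches `mirna` (case-insensitive).
#' Duplicate lines are collapsed with a logged count.
#'
#' @param path path to the TSV.
#' @param provenance provenance tag recorded on every pair.
#' @return a [TargetMap].
#' @export
read_target_table <- function(path, provenance = "table") {
  if (!file.exists(path)) sn_stop("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty target table: ", path, call. = FALSE)
    return(TargetMap())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    sn_stop("malformed line %d in %s (expected 2 tab-separated fields)",
            which(nf < 2L)[1L], path)
  }
  m <- vapply(fields, `[`, character(1L), 1L)
  g <- vapply(fields, `[`, character(1L), 2L)
  if (grepl("mirna|mir_id", m[1L], ignore.case = TRUE)) {
    m <- m[-1L]
    g <- g[-1L]
  }
  ndup <- sum(duplicated(paste(m, g, sep = "\r")))
  if (ndup) sn_log("read_target_table: collapsed %d duplicate pair(s)", ndup)
  TargetMap(m, g, provenance = provenance)
}

#' Write a target map to TSV
#' @param tm a [TargetMap].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(tm, path) {
  stopifnot(inherits(tm, "TargetMap"))
  utils::write.table(tm$pairs[, c("mirna_id", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("mirna_id", "gene_id"))
  invisible(path)
}

#' Union of two target maps
#'
#' Pairs present in both keep the provenance of the first map.
#'
#' @param tm1,tm2 [TargetMap] objects.
#' @return the combined [TargetMap].
#' @export
target_map_union <- function(tm1, tm2) {
  stopifnot(inherits(tm1, "TargetMap"), inherits(tm2, "TargetMap"))
  p <- rbind(tm1$pairs, tm2$pairs)
  TargetMap(p$mirna_id, p$gene_id, provenance = p$provenance)
}
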