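#' Seed region of a miRNA
#'
#' Nucleotides 2-7 from the 5' end of the mature miRNA sequence, the
#' region whose exact complementarity to a transcript defines a binding
#' site here (the 6-mer site class).
#'
#' @param seq miRNA sequence, RNA alphabet `A/C/G/U`, 5' to 3',
#'   length >= 8. Case-insensitive; `T` is accepted and read as `U`.
#' @return the 6-letter RNA seed string.
#' @examples
#' seed_of("UAGCUUAUCAGACUGAUGUUGA")  # "AGCUUA"
#' @export
seed_of <- function(seq) {
  s <- chartr("T", "U", toupper(as.character(seq)))
  if (nchar(s) < 8L) {
    sn_stop("miRNA sequence too short (%d nt; need >= 8 so the seed 2-7 exists)",
            nchar(s))
  }
  if (grepl("[^ACGU]", s)) {
    sn_stop("invalid miRNA alphabet in '%s' (expected A/C/G/U)", s)
  }
  substr(s, 2L, 7L)
}

# DNA reverse complement of an RNA seed: the 6-mer a transcript must
# contain to base-pair with the seed.
.seed_site_dna <- function(seed_rna) {
  rc <- Biostrings::reverseComplement(Biostrings::RNAString(seed_rna))
  as.character(Biostrings::DNAString(rc))
}

# normalize a transcript sequence to uppercase DNA over {A,C,G,T,N}
.normalize_dna <- function(seq, id = "?") {
  s <- chartr("U", "T", toupper(as.character(seq)))
  if (grepl("[^ACGTN]", s)) {
    sn_stop("invalid transcript alphabet in '%s' (expected A/C/G/T/N)", id)
  }
  s
}

#' Find seed-match sites in a transcript
#'
#' All (possibly overlapping) exact occurrences of the DNA reverse
#' complement of the miRNA seed in the target sequence. `N` never
#' matches.
#'
#' @param mirna_seq miRNA sequence (RNA alphabet, see [seed_of()]).
#' @param target_seq transcript sequence, DNA alphabet `A/C/G/T/N`
#'   (`U` accepted and read as `T`); for mRNAs typically the 3' UTR, for
#'   lncRNAs the whole transcript.
#' @param gene_id identifier recorded on each site.
#' @return data.frame with columns `gene_id`, `position` (0-based offset
#'   of the site), `site_seq` (the DNA 6-mer); zero rows when no site.
#' @export
find_seed_sites <- function(mirna_seq, target_seq, gene_id = NA_character_) {
  site <- .seed_site_dna(seed_of(mirna_seq))
  subject <- Biostrings::DNAString(.normalize_dna(target_seq, gene_id))
  hits <- Biostrings::matchPattern(site, subject, fixed = TRUE)
  starts <- Biostrings::start(hits)
  data.frame(gene_id = rep(as.character(gene_id), length(starts)),
             position = as.integer(starts) - 1L,
             site_seq = rep(site, length(starts)),
             stringsAsFactors = FALSE)
}

#' Read miRNA sequences from FASTA
#'
#' @param path FASTA of mature miRNA sequences (RNA alphabet; `T`
#'   tolerated).
#' @return named character vector of sequences (names = miRNA ids, first
#'   whitespace-delimited token of each header).
#' @export
read_mirna_fasta <- function(path) {
  if (!file.exists(path)) sn_stop("file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) sn_stop("empty FASTA: %s", path)
  seqs <- chartr("T", "U", toupper(as.character(ss)))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) sn_stop("duplicate ids in %s", path)
  seqs
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA of target transcript sequences (DNA alphabet; `U`
#'   tolerated).
#' @return named character vector of normalized DNA sequences.
#' @export
read_transcript_fasta <- function(path) {
  if (!file.exists(path)) sn_stop("file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) sn_stop("empty FASTA: %s", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) sn_stop("duplicate ids in %s", path)
  seqs <- vapply(seq_along(ss), function(i) {
    .normalize_dna(as.character(ss[[i]]), ids[i])
  }, character(1L))
  stats::setNames(seqs, ids)
}

#' De-novo target map from sequences
#'
#' Scans every transcript for the seed site of every miRNA; a
#' (miRNA, gene) pair enters the map iff at least one exact seed-match
#' site is found. Pairs carry provenance `"seed_scan"`.
#'
#' @param mirnas named character vector of miRNA sequences
#'   (see [read_mirna_fasta()]).
#' @param targets named character vector of transcript sequences
#'   (see [read_transcript_fasta()]).
#' @return a [TargetMap].
#' @export
build_target_map_from_sequences <- function(mirnas, targets) {
  if (!length(mirnas)) sn_stop("no miRNA sequences supplied")
  if (!length(targets)) sn_stop("no transcript sequences supplied")
  if (is.null(names(mirnas)) || is.null(names(targets))) {
    sn_stop("sequences must be named by identifier")
  }
  subjects <- Biostrings::DNAStringSet(
    vapply(seq_along(targets),
           function(i) .normalize_dna(targets[i], names(targets)[i]),
           character(1L)))
  names(subjects) <- names(targets)
  m_out <- character()
  g_out <- character()
  for (mid in names(mirnas)) {
    site <- .seed_site_dna(seed_of(mirnas[[mid]]))
    nhit <- Biostrings::vcountPattern(site, subjects, fixed = TRUE)
    hit_genes <- names(subjects)[nhit > 0L]
    m_out <- c(m_out, rep(mid, length(hit_genes)))
    g_out <- c(g_out, hit_genes)
  }
  sn_log("build_target_map_from_sequences: %d pair(s) from %d miRNAs x %d transcripts",
         length(g_out), length(mirnas), length(targets))
  TargetMap(m_out, g_out, provenance = "seed_scan")
}

#' Annotate triplets with seed-match sharing
#'
#' A triplet (X, Y, Z) shares the binding site when both X and Y are
#' targets of Z in the map; only then can the pair genuinely compete for
#' Z. Sets the `seed_match` column to that conjunction.
#'
#' @param triplets data.frame from [score_triplets()].
#' @param tm a non-empty [TargetMap].
#' @return `triplets` with `seed_match` filled in.
#' @export
annotate_seed_match <- function(triplets, tm) {
  stopifnot(inherits(tm, "TargetMap"))
  if (!nrow(tm$pairs)) sn_stop("annotate_seed_match: empty TargetMap")
  if (!nrow(triplets)) return(triplets)
  triplets$seed_match <- has_target(tm, triplets$z_id, triplets$x_id) &
    has_target(tm, triplets$z_id, triplets$y_id)
  if (!any(triplets$seed_match)) {
    warning("no triplet shares binding sites for its miRNA", call. = FALSE)
  }
  triplets
}
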