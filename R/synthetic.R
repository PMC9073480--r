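#' Configuration for the synthetic sponge-data generator
#'
#' Defines a miniature transcriptome with planted structure on the log2
#' scale: sponge triplets where a miRNA Z drives both RNAs of a pair
#' (`x = -b z + e`, `y = -b z + e'`, `z ~ N(0,1)`, so the pair is highly
#' co-expressed yet nearly uncorrelated given Z), direct pairs driven by
#' a shared latent factor independent of every miRNA (high correlation,
#' sensitivity near zero), and independent background genes. Values are
#' exported on the raw scale as `2^value` so the pipeline's log2 step is
#' exercised end to end.
#'
#' @param n_samples number of paired samples (default 300).
#' @param n_mrna,n_lncrna,n_mirna feature counts (defaults 40 / 20 / 15).
#' @param n_sponge_triplets planted miRNA-mediated triplets (default 5).
#' @param n_direct_pairs planted latent-factor pairs (default 5).
#' @param mirna_effect regression weight `b` of each RNA on its miRNA
#'   (default 1; negative sign applied internally: repression biology).
#' @param direct_effect latent-factor weight of direct pairs (default
#'   0.8). Kept below `mirna_effect` so the two planted regimes are
#'   distinguishable: miRNA-mediated pairs occupy the extreme of the
#'   correlation distribution (about 0.92 at the defaults) while direct
#'   pairs are strongly but less extremely co-expressed (about 0.88),
#'   still far above the independent background.
#' @param noise_sd residual standard deviation (default 0.3; with `b = 1`
#'   the planted pair correlation is about `b^2 / (b^2 + noise_sd^2)`).
#' @param missing_rate uniform missing-entry rate in `[0, 1)`
#'   (default 0.02).
#' @param target_noise_pairs random decoy (miRNA, gene) interactions
#'   added to the target table beyond the planted ones (default 30).
#' @param transcript_length length of each simulated transcript
#'   (default 300 nt).
#' @param seed integer RNG seed; the whole dataset is a deterministic
#'   function of it.
#' @return validated list of class `sponge_sim_config`.
#' @export
sponge_sim_config <- function(n_samples = 300L, n_mrna = 40L,
                              n_lncrna = 20L, n_mirna = 15L,
                              n_sponge_triplets = 5L, n_direct_pairs = 5L,
                              mirna_effect = 1, direct_effect = 0.8,
                              noise_sd = 0.3,
                              missing_rate = 0.02,
                              target_noise_pairs = 30L,
                              transcript_length = 300L, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_mrna = as.integer(n_mrna),
              n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              n_sponge_triplets = as.integer(n_sponge_triplets),
              n_direct_pairs = as.integer(n_direct_pairs),
              mirna_effect = as.numeric(mirna_effect),
              direct_effect = as.numeric(direct_effect),
              noise_sd = as.numeric(noise_sd),
              missing_rate = as.numeric(missing_rate),
              target_noise_pairs = as.integer(target_noise_pairs),
              transcript_length = as.integer(transcript_length),
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_samples", "n_mrna", "n_lncrna", "n_mirna",
                         "n_sponge_triplets", "n_direct_pairs",
                         "target_noise_pairs")])
  if (any(counts < 0)) sn_stop("counts must be non-negative")
  if (cfg$n_sponge_triplets > min(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna)) {
    sn_stop("n_sponge_triplets exceeds min(n_mrna, n_lncrna, n_mirna)")
  }
  if (cfg$n_sponge_triplets + cfg$n_direct_pairs >
        min(cfg$n_mrna, cfg$n_lncrna)) {
    sn_stop("planted structures need distinct RNA pairs: reduce counts")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    sn_stop("missing_rate must be in [0, 1)")
  }
  if (cfg$noise_sd < 0) sn_stop("noise_sd must be >= 0")
  if (cfg$transcript_length < 20L) sn_stop("transcripts too short")
  class(cfg) <- "sponge_sim_config"
  cfg
}

.rand_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic sponge dataset
#'
#' Produces in-memory objects in exactly the shapes the pipeline reads
#' (see [write_sponge_dataset()] for the on-disk forms), plus a truth
#' table of planted structures for recovery evaluation.
#'
#' @param cfg a [sponge_sim_config()].
#' @return list with elements `rna` and `mirna` (raw-scale
#'   [ExpressionMatrix]), `annotation` (named biotype vector),
#'   `target_map` ([TargetMap]), `mirna_seqs` and `transcript_seqs`
#'   (named character vectors), `truth` (data.frame `x_id`, `y_id`,
#'   `z_id`, `kind`), and `config`.
#' @export
simulate_sponge_data <- function(cfg) {
  stopifnot(inherits(cfg, "sponge_sim_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_samples
  samples <- sprintf("S%03d", seq_len(ns))
  mrna_ids <- sprintf("mRNA_%03d", seq_len(cfg$n_mrna))
  lnc_ids <- sprintf("lncRNA_%03d", seq_len(cfg$n_lncrna))
  mir_ids <- sprintf("miR_%03d", seq_len(cfg$n_mirna))

  # centered log2-scale profiles; baselines added at export only
  Z <- matrix(stats::rnorm(cfg$n_mirna * ns), cfg$n_mirna, ns,
              dimnames = list(mir_ids, samples))
  M <- matrix(stats::rnorm(cfg$n_mrna * ns), cfg$n_mrna, ns,
              dimnames = list(mrna_ids, samples))
  L <- matrix(stats::rnorm(cfg$n_lncrna * ns), cfg$n_lncrna, ns,
              dimnames = list(lnc_ids, samples))

  b <- cfg$mirna_effect
  truth <- data.frame(x_id = character(), y_id = character(),
                      z_id = character(), kind = character(),
                      stringsAsFactors = FALSE)
  for (t in seq_len(cfg$n_sponge_triplets)) {
    z <- Z[t, ]
    M[t, ] <- -b * z + stats::rnorm(ns, sd = cfg$noise_sd)
    L[t, ] <- -b * z + stats::rnorm(ns, sd = cfg$noise_sd)
    truth <- rbind(truth, data.frame(x_id = mrna_ids[t],
                                     y_id = lnc_ids[t],
                                     z_id = mir_ids[t], kind = "sponge",
                                     stringsAsFactors = FALSE))
  }
  for (d in seq_len(cfg$n_direct_pairs)) {
    i <- cfg$n_sponge_triplets + d
    f <- stats::rnorm(ns)                 # latent factor, miRNA-independent
    M[i, ] <- cfg$direct_effect * f + stats::rnorm(ns, sd = cfg$noise_sd)
    L[i, ] <- cfg$direct_effect * f + stats::rnorm(ns, sd = cfg$noise_sd)
    truth <- rbind(truth, data.frame(x_id = mrna_ids[i],
                                     y_id = lnc_ids[i],
                                     z_id = NA_character_, kind = "direct",
                                     stringsAsFactors = FALSE))
  }

  # export on raw scale with per-feature baselines (log2 FPKM ~ 8);
  # shifts leave every correlation unchanged
  shift <- function(mat) {
    mat + stats::rnorm(nrow(mat), mean = 8, sd = 1)
  }
  rna_log <- rbind(shift(M), shift(L))
  mir_log <- shift(Z)
  rna_raw <- 2^rna_log
  mir_raw <- 2^mir_log
  if (cfg$missing_rate > 0) {
    rna_raw[stats::runif(length(rna_raw)) < cfg$missing_rate] <- NA_real_
    mir_raw[stats::runif(length(mir_raw)) < cfg$missing_rate] <- NA_real_
  }

  annotation <- stats::setNames(
    c(rep("protein_coding", cfg$n_mrna), rep("lncRNA", cfg$n_lncrna)),
    c(mrna_ids, lnc_ids))

  # planted target interactions plus random decoys
  tm_m <- character(); tm_g <- character()
  sp <- truth[truth$kind == "sponge", , drop = FALSE]
  if (nrow(sp)) {
    tm_m <- c(rbind(sp$z_id, sp$z_id))
    tm_g <- c(rbind(sp$x_id, sp$y_id))
  }
  all_genes <- c(mrna_ids, lnc_ids)
  n_decoy <- 0L
  guard <- 0L
  while (n_decoy < cfg$target_noise_pairs && guard < 10000L) {
    guard <- guard + 1L
    zm <- sample(mir_ids, 1L)
    gg <- sample(all_genes, 1L)
    if (any(tm_m == zm & tm_g == gg)) next
    tm_m <- c(tm_m, zm); tm_g <- c(tm_g, gg)
    n_decoy <- n_decoy + 1L
  }
  target_map <- TargetMap(tm_m, tm_g, provenance = "table")

  # sequences: unique seeds per miRNA, sites embedded for every mapped pair
  rna_alpha <- c("A", "C", "G", "U")
  dna_alpha <- c("A", "C", "G", "T")
  mirna_seqs <- character(cfg$n_mirna)
  seen_seeds <- character()
  for (i in seq_len(cfg$n_mirna)) {
    repeat {
      s <- .rand_seq(22L, rna_alpha)
      if (!(substr(s, 2L, 7L) %in% seen_seeds)) break
    }
    mirna_seqs[i] <- s
    seen_seeds <- c(seen_seeds, substr(s, 2L, 7L))
  }
  names(mirna_seqs) <- mir_ids
  transcript_seqs <- vapply(all_genes, function(g) {
    .rand_seq(cfg$transcript_length, dna_alpha)
  }, character(1L))
  for (i in seq_along(tm_m)) {
    site <- .seed_site_dna(seed_of(mirna_seqs[[tm_m[i]]]))
    tr <- transcript_seqs[[tm_g[i]]]
    pos <- sample.int(nchar(tr) - 6L, 1L)
    substr(tr, pos, pos + 5L) <- site
    transcript_seqs[[tm_g[i]]] <- tr
  }

  list(rna = ExpressionMatrix(rna_raw, scale = "raw"),
       mirna = ExpressionMatrix(mir_raw, scale = "raw"),
       annotation = annotation,
       target_map = target_map,
       mirna_seqs = mirna_seqs,
       transcript_seqs = transcript_seqs,
       truth = truth,
       config = cfg)
}

#' Write a synthetic dataset to disk
#'
#' Emits the exact file formats the pipeline reads: `rna.tsv`,
#' `mirna.tsv` (expression), `annotation.tsv`, `targets.tsv`,
#' `mirnas.fa`, `transcripts.fa`, and `truth.tsv`.
#'
#' @param sim a [simulate_sponge_data()] result.
#' @param dir output directory (created if absent).
#' @return named character vector of file paths.
#' @export
write_sponge_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    rna = file.path(dir, "rna.tsv"),
    mirna = file.path(dir, "mirna.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    targets = file.path(dir, "targets.tsv"),
    mirna_fasta = file.path(dir, "mirnas.fa"),
    transcript_fasta = file.path(dir, "transcripts.fa"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression(sim$rna, paths["rna"])
  write_expression(sim$mirna, paths["mirna"])
  utils::write.table(
    data.frame(gene_id = names(sim$annotation),
               biotype = unname(sim$annotation)),
    paths["annotation"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_target_table(sim$target_map, paths["targets"])
  writeLines(paste0(">", names(sim$mirna_seqs), "\n", sim$mirna_seqs),
             paths["mirna_fasta"])
  writeLines(paste0(">", names(sim$transcript_seqs), "\n",
                    sim$transcript_seqs), paths["transcript_fasta"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  paths
}

#' Precision and recall of planted sponges among top-ranked triplets
#'
#' Ranks triplets by decreasing sensitivity (ties broken by ids for
#' determinism) and scores the top `k` against the truth table's sponge
#' rows. A triplet hits when its unordered RNA pair and its miRNA match
#' a planted sponge.
#'
#' @param selected triplet data.frame (needs `x_id`, `y_id`, `z_id`,
#'   `sensitivity`).
#' @param truth truth table from [simulate_sponge_data()].
#' @param k number of top triplets scored.
#' @return list with `precision_at_k`, `recall_at_k`, `n_planted`,
#'   `hits` (the matching top-k rows).
#' @export
evaluate_recovery <- function(selected, truth, k) {
  stopifnot(k >= 1L)
  sponges <- truth[truth$kind == "sponge", , drop = FALSE]
  if (!nrow(sponges)) {
    warning("truth table has no planted sponges; precision set to 0",
            call. = FALSE)
    return(list(precision_at_k = 0, recall_at_k = NA_real_,
                n_planted = 0L, hits = selected[0, , drop = FALSE]))
  }
  ord <- order(-selected$sensitivity, selected$x_id, selected$y_id,
               selected$z_id, method = "radix")
  top <- selected[utils::head(ord, k), , drop = FALSE]
  canon <- function(a, b, z) {
    paste(pmin(a, b), pmax(a, b), z, sep = "\r")
  }
  truth_key <- canon(sponges$x_id, sponges$y_id, sponges$z_id)
  top_key <- canon(top$x_id, top$y_id, top$z_id)
  hit <- top_key %in% truth_key
  list(precision_at_k = sum(hit) / k,
       recall_at_k = length(intersect(top_key, truth_key)) /
         nrow(sponges),
       n_planted = nrow(sponges),
       hits = top[hit, , drop = FALSE])
}
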