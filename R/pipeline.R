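#' Pipeline configuration
#'
#' Collects and validates every knob of the end-to-end run. Defaults
#' follow the method's published settings: both selection thresholds at
#' the 99th percentile of the respective distribution, rows with more
#' than 10 percent missing samples removed.
#'
#' @param rna_path,mirna_path expression TSVs (raw normalized units).
#' @param annotation_path gene biotype TSV.
#' @param targets_path optional miRNA-target TSV (enables seed-match
#'   annotation and enrichment).
#' @param mirna_fasta,transcript_fasta optional FASTA paths; when both
#'   are given a de-novo seed-scan target map is built and unioned with
#'   the table.
#' @param class_a,class_b biotype labels of the two candidate-ceRNA
#'   classes (defaults `protein_coding` vs `lncRNA`).
#' @param corr_quantile,sens_quantile percentile thresholds in (0, 1)
#'   for pair correlation and triplet sensitivity (defaults 0.99).
#' @param max_missing_fraction missingness cut-off (default 0.10).
#' @param min_overlap minimum complete-sample overlap per correlation.
#' @param pseudocount offset for the log2 transform.
#' @param seed_filter restrict network edges to triplets sharing the
#'   miRNA's binding sites.
#' @param use_absolute_corr threshold `|rho|` instead of signed rho.
#' @param require_negative_mirna_corr require the miRNA to be negatively
#'   correlated with both RNAs of a triplet.
#' @param triplet_budget hard cap on candidate triplets.
#' @param max_block_rows RNA pairs per sensitivity block file.
#' @param out_dir output directory.
#' @return validated list of class `sponge_config`.
#' @export
sponge_config <- function(rna_path, mirna_path, annotation_path,
                          targets_path = NULL, mirna_fasta = NULL,
                          transcript_fasta = NULL,
                          class_a = "protein_coding", class_b = "lncRNA",
                          corr_quantile = 0.99, sens_quantile = 0.99,
                          max_missing_fraction = 0.10, min_overlap = 10L,
                          pseudocount = 0, seed_filter = FALSE,
                          use_absolute_corr = FALSE,
                          require_negative_mirna_corr = FALSE,
                          triplet_budget = 1e7, max_block_rows = 5000L,
                          out_dir = "spongenet_out") {
  cfg <- list(rna_path = rna_path, mirna_path = mirna_path,
              annotation_path = annotation_path,
              targets_path = targets_path, mirna_fasta = mirna_fasta,
              transcript_fasta = transcript_fasta, class_a = class_a,
              class_b = class_b, corr_quantile = corr_quantile,
              sens_quantile = sens_quantile,
              max_missing_fraction = max_missing_fraction,
              min_overlap = as.integer(min_overlap),
              pseudocount = pseudocount, seed_filter = seed_filter,
              use_absolute_corr = use_absolute_corr,
              require_negative_mirna_corr = require_negative_mirna_corr,
              triplet_budget = triplet_budget,
              max_block_rows = as.integer(max_block_rows),
              out_dir = out_dir)
  for (q in c("corr_quantile", "sens_quantile")) {
    v <- cfg[[q]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      sn_stop("%s must be a single value in (0, 1); got %s", q,
              paste(v, collapse = ","))
    }
  }
  if (cfg$max_missing_fraction < 0 || cfg$max_missing_fraction > 1) {
    sn_stop("max_missing_fraction must be in [0, 1]")
  }
  if (cfg$pseudocount < 0) sn_stop("pseudocount must be >= 0")
  if (cfg$min_overlap < 3L) sn_stop("min_overlap must be >= 3")
  for (p in c("rna_path", "mirna_path", "annotation_path", "targets_path",
              "mirna_fasta", "transcript_fasta")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      sn_stop("%s does not exist: %s", p, cfg[[p]])
    }
  }
  if (cfg$seed_filter && is.null(cfg$targets_path) &&
        (is.null(cfg$mirna_fasta) || is.null(cfg$transcript_fasta))) {
    sn_stop("seed_filter requires targets_path or both FASTA inputs")
  }
  class(cfg) <- "sponge_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [sponge_config()] arguments.
#' @param ... overrides applied on top of the file (flags win).
#' @return a `sponge_config`.
#' @export
read_sponge_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(sponge_config, vals)
}

#' Run the full ceRNA-network pipeline
#'
#' Read and preprocess -> cross-class Pearson correlations -> pair
#' selection -> triplet scoring (partial and sensitivity correlation) ->
#' sensitivity-block export -> triplet selection -> optional seed-match
#' annotation and per-miRNA enrichment -> network assembly and export.
#' Writes `pairs.tsv` (selected pairs), `triplets.tsv` (selected
#' triplets), `sensitivity_block_NNN.tsv`, `enrichment.tsv` (when a
#' target map is available), the network files, and `manifest.yaml`
#' echoing the configuration, the thresholds used, and every stage
#' count. Identical configuration and inputs give identical outputs.
#'
#' @param cfg a [sponge_config()].
#' @return invisibly, a list with the principal intermediate objects
#'   (`pairs`, `pairs_selected`, `triplets`, `triplets_selected`,
#'   `enrichment`, `network`, `manifest`, `files`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "sponge_config"))
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  sn_log("stage io_preprocess: reading inputs")
  rna_raw <- read_expression(cfg$rna_path, scale = "raw")
  mir_raw <- read_expression(cfg$mirna_path, scale = "raw")
  ann <- read_biotype_annotation(cfg$annotation_path)
  al <- align_samples(rna_raw, mir_raw)
  parts <- partition_by_biotype(al$rna, ann, cfg$class_a, cfg$class_b)
  a <- filter_missing(log2_transform(parts$a, cfg$pseudocount),
                      cfg$max_missing_fraction)
  b <- filter_missing(log2_transform(parts$b, cfg$pseudocount),
                      cfg$max_missing_fraction)
  mir <- filter_missing(log2_transform(al$mirna, cfg$pseudocount),
                        cfg$max_missing_fraction)

  sn_log("stage correlation: %d x %d candidate pairs, %d miRNAs",
         nrow(a), nrow(b), nrow(mir))
  pairs <- pairwise_correlation(a, b, cfg$min_overlap)
  sel_pairs <- select_pairs(pairs, cfg$corr_quantile,
                            cfg$use_absolute_corr)
  if (!nrow(sel_pairs)) sn_stop("stage correlation: no pairs selected")
  rna_all <- .as_expr(rbind(unclass(a), unclass(b)), "log2")
  triplets <- score_triplets(sel_pairs, mir, rna_all, cfg$min_overlap,
                             cfg$triplet_budget)

  tm <- NULL
  if (!is.null(cfg$targets_path)) {
    tm <- read_target_table(cfg$targets_path)
  }
  if (!is.null(cfg$mirna_fasta) && !is.null(cfg$transcript_fasta)) {
    tm_scan <- build_target_map_from_sequences(
      read_mirna_fasta(cfg$mirna_fasta),
      read_transcript_fasta(cfg$transcript_fasta))
    tm <- if (is.null(tm)) tm_scan else target_map_union(tm, tm_scan)
  }
  if (!is.null(tm) && nrow(tm$pairs)) {
    triplets <- annotate_seed_match(triplets, tm)
  }

  sm <- sensitivity_matrix(triplets)
  block_files <- chunk_sensitivity(sm, cfg$max_block_rows, out)
  sel_trip <- select_triplets(triplets, cfg$sens_quantile,
                              cfg$require_negative_mirna_corr)
  if (!nrow(sel_trip)) sn_stop("stage selection: no triplets selected")

  enr <- NULL
  if (!is.null(tm) && nrow(tm$pairs)) {
    enr <- enrich_all(triplets, sel_trip, tm)
    utils::write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  net <- build_network(sel_trip, seed_filter = cfg$seed_filter,
                       enrichment = enr, annotation = ann)
  net_files <- export_network(net, out)
  comps <- connected_components(net)
  hubs <- find_hubs(net)
  sn_log("stage network: %d component(s), %d hub(s)", length(comps),
         nrow(hubs))

  utils::write.table(sel_pairs, file.path(out, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sel_trip, file.path(out, "triplets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")

  manifest <- list(
    tool = "spongenet",
    version = as.character(utils::packageVersion("spongenet")),
    config = lapply(unclass(cfg), function(x) if (is.null(x)) NA else x),
    thresholds = list(
      pair_correlation = as.numeric(attr(sel_pairs, "threshold")),
      sensitivity = as.numeric(attr(sel_trip, "threshold"))),
    counts = list(
      samples = ncol(a),
      class_a_features = nrow(a), class_b_features = nrow(b),
      mirnas = nrow(mir),
      pairs_total = nrow(pairs), pairs_selected = nrow(sel_pairs),
      triplets_scored = nrow(triplets),
      triplets_selected = nrow(sel_trip),
      nodes = nrow(net$nodes), edges = nrow(net$edges),
      components = length(comps), hubs = nrow(hubs))
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

  invisible(list(pairs = pairs, pairs_selected = sel_pairs,
                 triplets = triplets, triplets_selected = sel_trip,
                 enrichment = enr, network = net, components = comps,
                 hubs = hubs, manifest = manifest,
                 files = c(block_files, net_files,
                           pairs = file.path(out, "pairs.tsv"),
                           triplets = file.path(out, "triplets.tsv"),
                           manifest = file.path(out, "manifest.yaml"))))
}
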