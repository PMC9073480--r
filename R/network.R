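#' Assemble the ceRNA interaction network
#'
#' Nodes are RNAs; an edge joins two RNAs whose co-expression survived
#' both the correlation and the sensitivity thresholds, with the
#' mediating miRNAs aggregated as an edge attribute. With
#' `seed_filter = TRUE` only triplets whose pair shares the miRNA's
#' binding site contribute (run [annotate_seed_match()] first).
#'
#' Edges are unordered: (x, y) and (y, x) collapse onto one edge whose
#' endpoints are stored in lexicographic order. The edge's `rho_xy` is
#' taken from its highest-sensitivity triplet; `max_sensitivity` is the
#' maximum over mediating miRNAs.
#'
#' @param triplets selected triplets ([select_triplets()] output).
#' @param seed_filter drop triplets without a shared seed match.
#' @param enrichment optional [enrich_all()] table; attaches the minimum
#'   per-miRNA enrichment p over an edge's mediators as `min_p`.
#' @param annotation optional named biotype vector for node attributes.
#' @return object of class `CeRNANetwork`: list with `nodes` and `edges`
#'   data.frames, the backing `triplets` table, and an igraph `graph`.
#' @export
build_network <- function(triplets, seed_filter = FALSE, enrichment = NULL,
                          annotation = NULL) {
  n_in <- nrow(triplets)
  if (!n_in) sn_stop("build_network: no surviving triplets supplied")
  if (any(triplets$x_id == triplets$y_id)) {
    sn_stop("build_network: self-loop triplet(s) present (x_id == y_id)")
  }
  tk <- triplets
  if (seed_filter) {
    if (all(is.na(tk$seed_match))) {
      sn_stop("seed_filter = TRUE but triplets lack seed-match annotation")
    }
    tk <- tk[!is.na(tk$seed_match) & tk$seed_match, , drop = FALSE]
  }
  if (!nrow(tk)) {
    sn_stop(paste0("zero triplets survive: %d selected, %d with shared ",
                   "seed match"), n_in,
            sum(triplets$seed_match %in% TRUE))
  }
  # canonical unordered endpoints
  swap <- tk$x_id > tk$y_id
  n1 <- ifelse(swap, tk$y_id, tk$x_id)
  n2 <- ifelse(swap, tk$x_id, tk$y_id)
  key <- paste(n1, n2, sep = "\r")
  ord <- order(key, tk$z_id, method = "radix")
  tk <- tk[ord, , drop = FALSE]
  n1 <- n1[ord]; n2 <- n2[ord]; key <- key[ord]

  pm <- if (!is.null(enrichment)) {
    stats::setNames(enrichment$p_value, enrichment$z_id)
  }
  edges <- do.call(rbind, lapply(split(seq_along(key), key), function(i) {
    tt <- tk[i, , drop = FALSE]
    best <- i[which.max(tt$sensitivity)]
    data.frame(
      node1 = n1[i[1L]], node2 = n2[i[1L]],
      mirnas = paste(sort(unique(tt$z_id)), collapse = ","),
      n_mirna = length(unique(tt$z_id)),
      rho_xy = tk$rho_xy[best],
      max_sensitivity = max(tt$sensitivity),
      min_p = if (is.null(pm)) NA_real_ else
        suppressWarnings(min(pm[unique(tt$z_id)], na.rm = TRUE)),
      stringsAsFactors = FALSE
    )
  }))
  edges <- edges[order(edges$node1, edges$node2, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges$min_p[!is.finite(edges$min_p)] <- NA_real_

  g <- igraph::graph_from_data_frame(
    edges[, c("node1", "node2")], directed = FALSE,
    vertices = sort(unique(c(edges$node1, edges$node2))))
  deg <- igraph::degree(g)
  nodes <- data.frame(
    id = igraph::V(g)$name,
    biotype = if (is.null(annotation)) NA_character_ else
      unname(annotation[igraph::V(g)$name]),
    degree = as.integer(unname(deg)),
    stringsAsFactors = FALSE
  )
  sn_log("build_network: %d nodes, %d edges from %d triplets%s",
         nrow(nodes), nrow(edges), nrow(tk),
         if (seed_filter) " (seed-filtered)" else "")
  structure(list(nodes = nodes, edges = edges, triplets = tk, graph = g),
            class = "CeRNANetwork")
}

#' @export
print.CeRNANetwork <- function(x, ...) {
  cat(sprintf("CeRNANetwork: %d nodes, %d edges, %d backing triplets\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$triplets)))
  invisible(x)
}

#' Connected components of a ceRNA network
#'
#' @param net a [build_network()] result.
#' @return list of components sorted by node count (then smallest node
#'   id), each a list with `nodes` (sorted ids) and `n_edges`.
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "CeRNANetwork"))
  comp <- igraph::components(net$graph)
  member <- comp$membership
  e_comp <- member[net$edges$node1]      # both endpoints share a component
  out <- lapply(seq_len(comp$no), function(ci) {
    list(nodes = sort(names(member)[member == ci]),
         n_edges = sum(e_comp == ci))
  })
  sizes <- vapply(out, function(cc) length(cc$nodes), integer(1L))
  first <- vapply(out, function(cc) cc$nodes[1L], character(1L))
  out[order(-sizes, first, method = "radix")]
}

#' Network hubs
#'
#' Nodes with strictly more than `min_links` links, the conventional hub
#' cut-off in this literature.
#'
#' @param net a [build_network()] result.
#' @param min_links degree must exceed this (default 5).
#' @return data.frame `id`, `degree`, sorted by decreasing degree, ties
#'   broken by identifier.
#' @export
find_hubs <- function(net, min_links = 5L) {
  stopifnot(inherits(net, "CeRNANetwork"))
  h <- net$nodes[net$nodes$degree > min_links, c("id", "degree"),
                 drop = FALSE]
  h <- h[order(-h$degree, h$id, method = "radix"), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Export a ceRNA network for Cytoscape
#'
#' Writes any of:
#' \describe{
#'   \item{sif}{`network.sif`, one interaction line `x <mirna> y` per
#'     backing triplet so Cytoscape can color edges by miRNA. Fields are
#'     space-separated unless an identifier contains a space, in which
#'     case the whole file switches to tab separators (SIF dialect rule).}
#'   \item{tsv}{`edges.tsv` / `nodes.tsv` attribute tables;
#'     [import_network()] reconstructs the network from them.}
#'   \item{graphml}{`network.graphml` with all node and edge attributes.}
#' }
#'
#' @param net a [build_network()] result.
#' @param out_dir output directory (created if absent).
#' @param fmts subset of `c("sif", "tsv", "graphml")`.
#' @return named character vector of written file paths.
#' @export
export_network <- function(net, out_dir,
                           fmts = c("sif", "tsv", "graphml")) {
  stopifnot(inherits(net, "CeRNANetwork"))
  bad <- setdiff(fmts, c("sif", "tsv", "graphml"))
  if (length(bad)) sn_stop("unknown export format(s): %s",
                           paste(bad, collapse = ", "))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) sn_stop("cannot create output directory: %s", out_dir)
  }
  paths <- character()
  if ("sif" %in% fmts) {
    ids <- c(net$triplets$x_id, net$triplets$z_id, net$triplets$y_id)
    sep <- if (any(grepl(" ", ids, fixed = TRUE))) "\t" else " "
    p <- file.path(out_dir, "network.sif")
    writeLines(paste(net$triplets$x_id, net$triplets$z_id,
                     net$triplets$y_id, sep = sep), p)
    paths["sif"] <- p
  }
  if ("tsv" %in% fmts) {
    pe <- file.path(out_dir, "edges.tsv")
    pn <- file.path(out_dir, "nodes.tsv")
    utils::write.table(net$edges, pe, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    utils::write.table(net$nodes, pn, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    paths["edges"] <- pe
    paths["nodes"] <- pn
  }
  if ("graphml" %in% fmts) {
    g <- net$graph
    for (col in c("mirnas", "n_mirna", "rho_xy", "max_sensitivity",
                  "min_p")) {
      g <- igraph::set_edge_attr(g, col, value = net$edges[[col]])
    }
    g <- igraph::set_vertex_attr(g, "degree", value = net$nodes$degree)
    if (!all(is.na(net$nodes$biotype))) {
      g <- igraph::set_vertex_attr(g, "biotype",
                                   value = net$nodes$biotype)
    }
    p <- file.path(out_dir, "network.graphml")
    igraph::write_graph(g, p, format = "graphml")
    paths["graphml"] <- p
  }
  paths
}

#' Rebuild a network from exported attribute tables
#'
#' Inverse of the `tsv` export: reconstructs nodes, edges and graph from
#' `edges.tsv` (and `nodes.tsv` when present). The backing triplet table
#' is not part of the tables, so `triplets` is empty in the result.
#'
#' @param edges_path path to `edges.tsv`.
#' @param nodes_path optional path to `nodes.tsv`.
#' @return a `CeRNANetwork`.
#' @export
import_network <- function(edges_path, nodes_path = NULL) {
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE,
                             colClasses = c(node1 = "character",
                                            node2 = "character",
                                            mirnas = "character",
                                            n_mirna = "integer",
                                            rho_xy = "numeric",
                                            max_sensitivity = "numeric",
                                            min_p = "numeric"))
  need <- c("node1", "node2", "mirnas", "n_mirna", "rho_xy",
            "max_sensitivity", "min_p")
  if (!all(need %in% colnames(edges))) {
    sn_stop("edges table misses column(s): %s",
            paste(setdiff(need, colnames(edges)), collapse = ", "))
  }
  edges <- edges[order(edges$node1, edges$node2, method = "radix"),
                 need, drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("node1", "node2")], directed = FALSE,
    vertices = sort(unique(c(edges$node1, edges$node2))))
  nodes <- if (!is.null(nodes_path)) {
    nd <- utils::read.delim(nodes_path, stringsAsFactors = FALSE,
                            colClasses = c(id = "character",
                                           biotype = "character",
                                           degree = "integer"))
    nd[match(igraph::V(g)$name, nd$id), , drop = FALSE]
  } else {
    data.frame(id = igraph::V(g)$name, biotype = NA_character_,
               degree = unname(igraph::degree(g)),
               stringsAsFactors = FALSE)
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 triplets = data.frame(), graph = g),
            class = "CeRNANetwork")
}
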