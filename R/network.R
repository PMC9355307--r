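#' Evidence filter on circRNA-miRNA interactions
#'
#' Keeps interactions supported by at least `min_experiments` AGO
#' CLIP-seq experiments, optionally restricted to circRNAs with a known
#' catalogue id.
#'
#' @param edges Data frame with columns `circ_id`, `mirna`,
#'   `n_experiments`.
#' @param min_experiments Inclusive evidence threshold (default 2).
#' @param known_ids Optional vector of catalogue ids; when given, edges
#'   whose `circ_id` is not among them are dropped.
#' @return The kept subset of `edges`.
#' @export
filter_circ_mirna <- function(edges, min_experiments = 2,
                              known_ids = NULL) {
  if (any(edges$n_experiments < 1))
    stop("experiment counts must be >= 1")
  keep <- edges$n_experiments >= min_experiments
  if (!is.null(known_ids)) keep <- keep & edges$circ_id %in% known_ids
  edges[keep, , drop = FALSE]
}

#' Build the tripartite ceRNA network
#'
#' Nodes are restricted to the differentially expressed circRNAs
#' (`decs`), the miRNAs they bind after the evidence filter, and those
#' miRNAs' mRNA targets lying in the union of the contrast's DEGs and the
#' expressed PAR genes. miRNAs with no retained mRNA target are pruned,
#' as are circRNAs left without an edge. miRNA regulation direction is
#' unobserved and recorded as `"none"`.
#'
#' @param decs Data frame of differentially expressed circRNAs with
#'   columns `circ_id` (catalogue id), `direction` (`"up"`/`"down"`),
#'   and optionally `log2FC`.
#' @param kept_circ_mirna Evidence-filtered edges from
#'   [filter_circ_mirna()].
#' @param mirna_targets Data frame with columns `mirna`, `gene_id`.
#' @param degs Data frame of differentially expressed genes with
#'   `gene_id`, `direction`, optionally `log2FC`.
#' @param expressed_par_genes Character vector of PAR gene ids passing
#'   the expression prefilter (kept as targets regardless of DEG status).
#' @return An object of class `"cerna_network"`: list with data frames
#'   `nodes` (`id`, `type`, `direction`, `significant`, `log2FC`) and
#'   `edges` (`from`, `to`, `type`, `evidence`).
#' @export
build_network <- function(decs, kept_circ_mirna, mirna_targets, degs,
                          expressed_par_genes = character(0)) {
  empty <- function() {
    structure(list(
      nodes = data.frame(id = character(), type = character(),
                         direction = character(), significant = logical(),
                         log2FC = numeric(), stringsAsFactors = FALSE),
      edges = data.frame(from = character(), to = character(),
                         type = character(), evidence = numeric(),
                         stringsAsFactors = FALSE)),
      class = "cerna_network")
  }
  if (is.null(decs) || nrow(decs) == 0) return(empty())
  cm <- kept_circ_mirna[kept_circ_mirna$circ_id %in% decs$circ_id, ,
                        drop = FALSE]
  if (nrow(cm) == 0) return(empty())
  allowed <- union(degs$gene_id, expressed_par_genes)
  mt <- mirna_targets[mirna_targets$mirna %in% cm$mirna &
                        mirna_targets$gene_id %in% allowed, , drop = FALSE]
  mt <- unique(mt[, c("mirna", "gene_id")])
  cm <- cm[cm$mirna %in% mt$mirna, , drop = FALSE]  # prune barren miRNAs
  if (nrow(cm) == 0) return(empty())

  gene_dir <- function(g) {
    d <- degs$direction[match(g, degs$gene_id)]
    ifelse(is.na(d), "none", d)
  }
  gene_lfc <- function(g) {
    if (is.null(degs$log2FC)) return(rep(NA_real_, length(g)))
    degs$log2FC[match(g, degs$gene_id)]
  }
  circ_ids <- unique(cm$circ_id)
  mirna_ids <- unique(cm$mirna)
  gene_ids <- unique(mt$gene_id)
  nodes <- rbind(
    data.frame(id = circ_ids, type = "circRNA",
               direction = decs$direction[match(circ_ids, decs$circ_id)],
               significant = TRUE,
               log2FC = if (is.null(decs$log2FC)) NA_real_
                 else decs$log2FC[match(circ_ids, decs$circ_id)],
               stringsAsFactors = FALSE),
    data.frame(id = mirna_ids, type = "miRNA", direction = "none",
               significant = FALSE, log2FC = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(id = gene_ids, type = "mRNA",
               direction = gene_dir(gene_ids),
               significant = gene_ids %in% degs$gene_id,
               log2FC = gene_lfc(gene_ids), stringsAsFactors = FALSE))
  edges <- rbind(
    data.frame(from = cm$circ_id, to = cm$mirna, type = "sponges",
               evidence = cm$n_experiments, stringsAsFactors = FALSE),
    data.frame(from = mt$mirna, to = mt$gene_id, type = "targets",
               evidence = NA_real_, stringsAsFactors = FALSE))
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

# enumerate circ -> miRNA -> mRNA paths of a network
network_paths <- function(network) {
  sp <- network$edges[network$edges$type == "sponges", , drop = FALSE]
  tg <- network$edges[network$edges$type == "targets", , drop = FALSE]
  if (nrow(sp) == 0 || nrow(tg) == 0)
    return(data.frame(circ = character(), mirna = character(),
                      gene = character(), stringsAsFactors = FALSE))
  out <- merge(data.frame(circ = sp$from, mirna = sp$to,
                          stringsAsFactors = FALSE),
               data.frame(mirna = tg$from, gene = tg$to,
                          stringsAsFactors = FALSE),
               by = "mirna")
  out[, c("circ", "mirna", "gene")]
}

#' Sponge sign-consistency filter
#'
#' A circRNA sponging miRNAs derepresses the miRNAs' targets, so an
#' upregulated circRNA explains an upregulated target and vice versa.
#' The filter keeps a circ-miRNA-mRNA path only when the circRNA and
#' mRNA directions agree (the miRNA direction is unobserved and not
#' consulted), rebuilds the edge set from the surviving paths, and
#' prunes nodes left isolated. Idempotent.
#'
#' @param network A `"cerna_network"`.
#' @return The filtered `"cerna_network"`.
#' @export
sign_consistency_filter <- function(network) {
  paths <- network_paths(network)
  if (nrow(paths) == 0) return(network)
  dirn <- function(id) network$nodes$direction[match(id, network$nodes$id)]
  keep <- dirn(paths$circ) == dirn(paths$gene) &
    dirn(paths$circ) %in% c("up", "down")
  paths <- paths[keep, , drop = FALSE]
  sp <- unique(paths[, c("circ", "mirna")])
  tg <- unique(paths[, c("mirna", "gene")])
  ev <- network$edges
  edges <- rbind(
    data.frame(from = sp$circ, to = sp$mirna, type = "sponges",
               evidence = ev$evidence[match(paste(sp$circ, sp$mirna),
                                            paste(ev$from, ev$to))],
               stringsAsFactors = FALSE),
    data.frame(from = tg$mirna, to = tg$gene, type = "targets",
               evidence = NA_real_, stringsAsFactors = FALSE))
  live <- unique(c(edges$from, edges$to))
  nodes <- network$nodes[network$nodes$id %in% live, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' Hypergeometric over-representation of network genes
#'
#' One-sided over-representation test of the network's mRNA set against
#' each gene set: `p = P(X >= k)` for `X ~ Hypergeometric(N = |universe|,
#' K = |set in universe|, n = |network genes|)`, BH-adjusted across sets.
#' Sets disjoint from the universe are skipped with a warning.
#'
#' @param network_genes Character vector of network mRNA ids (must be a
#'   subset of `universe`).
#' @param universe Background gene ids (e.g. all genes passing the
#'   expression prefilter in that tissue).
#' @param gene_sets Named list of character vectors.
#' @return Data frame (`set`, `overlap`, `set_size`, `odds`, `p`, `q`),
#'   one row per testable set.
#' @export
enrichment_test <- function(network_genes, universe, gene_sets) {
  if (!all(network_genes %in% universe))
    stop("network genes must be a subset of the universe")
  N <- length(unique(universe))
  n <- length(unique(network_genes))
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    if (K == 0) {
      warning("gene set '", nm, "' is disjoint from the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(network_genes, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    odds <- (k * (N - K - n + k)) / max((n - k) * (K - k), 0.5)
    data.frame(set = nm, overlap = k, set_size = K, odds = odds, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), odds = numeric(),
                      p = numeric(), q = numeric()))
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Export a ceRNA network to Cytoscape-ingestible files
#'
#' Writes a SIF file (`source interaction target`), a node-attribute TSV
#' (id, type, direction, significance, log2FC), an edge-list TSV, and a
#' GraphML file. The edge-list/node TSV pair round-trips through
#' [read_network_files()].
#'
#' @param network A `"cerna_network"`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"network"`).
#' @return Invisibly, the named vector of file paths written.
#' @export
export_network <- function(network, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sif = file.path(dir, paste0(prefix, ".sif")),
             nodes = file.path(dir, paste0(prefix, ".nodes.tsv")),
             edges = file.path(dir, paste0(prefix, ".edges.tsv")),
             graphml = file.path(dir, paste0(prefix, ".graphml")))
  sif <- if (nrow(network$edges))
    paste(network$edges$from, network$edges$type, network$edges$to)
  else character(0)
  writeLines(sif, paths["sif"])
  utils::write.table(network$nodes, paths["nodes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, paths["edges"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(network$nodes)) {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("from", "to", "type", "evidence")],
      directed = TRUE, vertices = network$nodes)
    igraph::write_graph(g, paths["graphml"], format = "graphml")
  } else writeLines(character(0), paths["graphml"])
  invisible(paths)
}

#' Read a network back from its exported node/edge tables
#'
#' @param nodes_path,edges_path Paths written by [export_network()].
#' @return A `"cerna_network"`.
#' @export
read_network_files <- function(nodes_path, edges_path) {
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0)
    nodes <- data.frame(id = character(), type = character(),
                        direction = character(), significant = logical(),
                        log2FC = numeric(), stringsAsFactors = FALSE)
  if (nrow(edges) == 0)
    edges <- data.frame(from = character(), to = character(),
                        type = character(), evidence = numeric(),
                        stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}
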