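# Regulatory-network construction and export. Nodes are miRNAs, genes and
# enriched terms; typed edges are miRNA-targets->gene, gene-annotated->term
# and gene-interacts-gene (external interaction tables, BioGRID-style).
# Exports speak the Cytoscape SIF dialect and GraphML (via igraph).

new_regulatory_network <- function(nodes, edges) {
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Regulatory network:", nrow(x$nodes), "nodes (",
      paste(names(table(x$nodes$node_type)), table(x$nodes$node_type),
            sep = ":", collapse = " "), "),",
      nrow(x$edges), "edges (",
      paste(names(table(x$edges$edge_type)), table(x$edges$edge_type),
            sep = ":", collapse = " "), ")\n")
  invisible(x)
}

empty_edges <- function() {
  data.frame(source = character(0), target = character(0),
             edge_type = character(0), stringsAsFactors = FALSE)
}

#' Build the miRNA-gene-term regulatory network
#'
#' Nodes are the miRNAs and genes of the negative-regulation pairs plus
#' the enriched terms (by default the top 8 per namespace); edges are
#' `targets` (miRNA -> gene) for every pair and `annotated` (gene -> term)
#' for every annotation of an included gene to an included term. Gene and
#' miRNA nodes carry an up/down direction from their fold-change signs.
#'
#' @param negative_pairs data.frame from [correlate_pairs()] (columns
#'   `mirna`, `mrna`, `x`, `y`); typically pre-filtered to
#'   `negative_regulation`.
#' @param enrichment data.frame from [enrich()].
#' @param annotation data.frame with columns `term`, `gene`.
#' @param fc_mrna differential results for mRNAs ([call_differential()]);
#'   used for the gene direction attribute.
#' @param top_terms number of enriched terms per namespace to include
#'   (`Inf` for all).
#' @return a `regulatory_network`.
#' @export
build_network <- function(negative_pairs, enrichment, annotation, fc_mrna,
                          top_terms = 8L) {
  pairs <- as.data.frame(negative_pairs)
  if (nrow(pairs) == 0) {
    return(new_regulatory_network(
      data.frame(id = character(0), node_type = character(0),
                 direction = character(0), stringsAsFactors = FALSE),
      empty_edges()))
  }
  genes <- unique(pairs$mrna)
  mirnas <- unique(pairs$mirna)
  unknown <- setdiff(genes, fc_mrna$feature_id)
  if (length(unknown)) {
    stop("pair references unknown gene(s): ",
         paste(unknown, collapse = ", "))
  }
  terms <- if (!is.null(enrichment) && nrow(enrichment) > 0) {
    kept <- if (is.finite(top_terms)) top_k(enrichment, top_terms)
            else enrichment
    unique(kept$term)
  } else character(0)

  dir_of <- function(v) ifelse(v > 0, "up", ifelse(v < 0, "down", "na"))
  gene_fc <- fc_mrna$log2fc[match(genes, fc_mrna$feature_id)]
  mirna_dir <- vapply(mirnas, function(m) {
    dir_of(pairs$y[match(m, pairs$mirna)])
  }, character(1))

  nodes <- rbind(
    data.frame(id = mirnas, node_type = "miRNA",
               direction = unname(mirna_dir), stringsAsFactors = FALSE),
    data.frame(id = genes, node_type = "gene",
               direction = dir_of(gene_fc), stringsAsFactors = FALSE),
    if (length(terms)) {
      data.frame(id = terms, node_type = "term", direction = "na",
                 stringsAsFactors = FALSE)
    })
  target_edges <- data.frame(source = pairs$mirna, target = pairs$mrna,
                             edge_type = "targets", stringsAsFactors = FALSE)
  ann <- as.data.frame(annotation)
  ann <- unique(ann[ann$gene %in% genes & ann$term %in% terms,
                    c("gene", "term"), drop = FALSE])
  annotated_edges <- if (nrow(ann)) {
    data.frame(source = ann$gene, target = ann$term,
               edge_type = "annotated", stringsAsFactors = FALSE)
  } else empty_edges()
  edges <- unique(rbind(target_edges, annotated_edges))
  new_regulatory_network(nodes, edges)
}

#' Merge external gene-gene interaction edges
#'
#' Adds `interacts` edges from a two-column gene-pair table (BioGRID-style
#' export). By default an edge is added only when BOTH endpoints already
#' exist as gene nodes; with `expand = TRUE` first-neighbor genes are
#' added as new nodes. Self-loops are dropped and duplicate interactions
#' (in either orientation) are deduplicated.
#'
#' @param network a `regulatory_network`.
#' @param edge_table data.frame whose first two columns are interacting
#'   gene symbols.
#' @param expand add first-neighbor genes absent from the network.
#' @param case_insensitive match gene symbols case-insensitively.
#' @return the augmented `regulatory_network`.
#' @export
merge_interactions <- function(network, edge_table, expand = FALSE,
                               case_insensitive = FALSE) {
  stopifnot(inherits(network, "regulatory_network"))
  tab <- as.data.frame(edge_table)
  if (ncol(tab) < 2) stop("edge table needs two columns of gene symbols")
  a <- as.character(tab[[1]])
  b <- as.character(tab[[2]])
  malformed <- is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b)
  if (nrow(tab) > 0 && mean(malformed) > 0.1) {
    stop("more than 10% of interaction rows are malformed (",
         sum(malformed), "/", length(malformed), ")")
  }
  if (any(malformed)) {
    warning("skipping ", sum(malformed), " malformed interaction row(s)")
    a <- a[!malformed]
    b <- b[!malformed]
  }
  gene_nodes <- network$nodes$id[network$nodes$node_type == "gene"]
  canon <- function(x) if (case_insensitive) toupper(x) else x
  match_node <- function(x) {
    idx <- match(canon(x), canon(gene_nodes))
    ifelse(is.na(idx), x, gene_nodes[idx])
  }
  a <- match_node(a)
  b <- match_node(b)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  present <- function(x) canon(x) %in% canon(gene_nodes)
  if (!expand) {
    keep <- present(a) & present(b)
  } else {
    keep <- present(a) | present(b)
  }
  a <- a[keep]
  b <- b[keep]
  # deduplicate as unordered pairs, and against existing interacts edges
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  existing <- network$edges[network$edges$edge_type == "interacts", ]
  existing_key <- paste(pmin(existing$source, existing$target),
                        pmax(existing$source, existing$target), sep = "\r")
  fresh <- !duplicated(key) & !(key %in% existing_key)
  new_edges <- data.frame(source = lo[fresh], target = hi[fresh],
                          edge_type = if (sum(fresh)) "interacts"
                                      else character(0),
                          stringsAsFactors = FALSE)
  new_nodes <- setdiff(unique(c(new_edges$source, new_edges$target)),
                       network$nodes$id)
  nodes <- rbind(network$nodes,
                 if (length(new_nodes)) {
                   data.frame(id = new_nodes, node_type = "gene",
                              direction = "na", stringsAsFactors = FALSE)
                 })
  new_regulatory_network(nodes, rbind(network$edges, new_edges))
}

sif_quote <- function(x) {
  needs <- grepl("[[:space:]]", x)
  x[needs] <- paste0("\"", x[needs], "\"")
  x
}

sif_unquote <- function(x) sub("^\"(.*)\"$", "\\1", x)

network_to_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "edge_type")],
    directed = TRUE, vertices = network$nodes)
  g
}

igraph_to_network <- function(g) {
  nodes <- data.frame(id = igraph::V(g)$name,
                      node_type = igraph::V(g)$node_type,
                      direction = igraph::V(g)$direction,
                      stringsAsFactors = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- if (nrow(el)) {
    data.frame(source = el$from, target = el$to,
               edge_type = el$edge_type, stringsAsFactors = FALSE)
  } else empty_edges()
  new_regulatory_network(nodes, edges)
}

#' Export a regulatory network
#'
#' `sif` writes one `source<TAB>edge_type<TAB>target` line per edge (ids
#' containing whitespace are double-quoted); `graphml` carries all node
#' and edge attributes (via igraph) and round-trips the network exactly;
#' `tsv` writes `<path>.nodes.tsv` and `<path>.edges.tsv`.
#'
#' @param network a `regulatory_network`.
#' @param path output path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(network, "regulatory_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- paste(sif_quote(network$edges$source),
                   network$edges$edge_type,
                   sif_quote(network$edges$target), sep = "\t")
    writeLines(lines, path)
  } else if (format == "graphml") {
    igraph::write_graph(network_to_igraph(network), path,
                        format = "graphml")
  } else {
    utils::write.table(network$nodes, paste0(path, ".nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(network$edges, paste0(path, ".edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a regulatory network written by [export_network()]
#'
#' GraphML import reproduces the network exactly; SIF import reproduces
#' the typed edge set (node attributes are not part of the SIF dialect,
#' so node types are inferred from edge types where possible).
#'
#' @param path file written by [export_network()].
#' @param format `"sif"` or `"graphml"`.
#' @return a `regulatory_network`.
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph_to_network(igraph::read_graph(path, format = "graphml")))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) stop("malformed SIF line(s): ", which(bad)[1])
  edges <- data.frame(source = sif_unquote(vapply(parts, `[`, "", 1)),
                      target = sif_unquote(vapply(parts, `[`, "", 3)),
                      edge_type = vapply(parts, `[`, "", 2),
                      stringsAsFactors = FALSE)
  type_from_edges <- function(id) {
    if (id %in% edges$source[edges$edge_type == "targets"]) return("miRNA")
    if (id %in% edges$target[edges$edge_type == "annotated"]) return("term")
    "gene"
  }
  ids <- unique(c(edges$source, edges$target))
  nodes <- data.frame(id = ids,
                      node_type = vapply(ids, type_from_edges, ""),
                      direction = "na", stringsAsFactors = FALSE)
  new_regulatory_network(nodes, edges)
}

#' Rank hub genes by degree
#'
#' Gene nodes sorted by total degree (all edge types, in plus out)
#' descending, ties broken by id ascending. A gene touching many others is
#' a candidate key node of the trait under study.
#'
#' @param network a `regulatory_network`.
#' @param top_n genes to return.
#' @return data.frame with columns `gene`, `degree`.
#' @export
hub_genes <- function(network, top_n = 10L) {
  stopifnot(inherits(network, "regulatory_network"))
  if (top_n < 1) stop("top_n must be >= 1")
  genes <- network$nodes$id[network$nodes$node_type == "gene"]
  if (length(genes) == 0) {
    return(data.frame(gene = character(0), degree = integer(0),
                      stringsAsFactors = FALSE))
  }
  deg <- vapply(genes, function(g) {
    sum(network$edges$source == g) + sum(network$edges$target == g)
  }, integer(1))
  out <- data.frame(gene = genes, degree = deg, stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
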