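#' Build a protein-interaction graph from an edge table
#'
#' Validates scores (integers in 0-1000), drops self-loops, and collapses
#' duplicate edges keeping the maximum score (with a message).
#'
#' @param edges data.frame with columns `a`, `b`, `combined_score` (as from
#'   [read_edges()]).
#' @return an [igraph::igraph] undirected graph with edge attribute
#'   `combined_score`.
#' @export
ppi_graph <- function(edges) {
  edges <- validate_edges(edges)
  lo <- pmin(edges$a, edges$b)
  hi <- pmax(edges$a, edges$b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    message("collapsing ", sum(duplicated(key)),
            " duplicate edge(s), keeping max score")
    sc <- tapply(edges$combined_score, key, max)
    first <- !duplicated(key)
    edges <- data.frame(a = lo[first], b = hi[first],
                        combined_score = as.integer(sc[key[first]]),
                        stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Filter a PPI graph by confidence score
#'
#' Keeps only edges whose combined score strictly exceeds `threshold`
#' (the "greater than 500" rule); nodes left without any edge are dropped.
#'
#' @param graph an igraph from [ppi_graph()].
#' @param threshold score cut (default 500, strict).
#' @return filtered igraph.
#' @export
filter_ppi <- function(graph, threshold = 500) {
  g <- igraph::subgraph_from_edges(
    graph, igraph::E(graph)[igraph::E(graph)$combined_score > threshold],
    delete.vertices = TRUE)
  g
}

#' Shortest-hop proximity of signature genes to drug targets
#'
#' For every signature gene, the unweighted shortest-path distance (hop
#' count) in the filtered graph to the nearest drug-target gene, the
#' identity of that target (ties broken by node id), and one shortest path.
#' Genes absent from the graph (or unable to reach any target) get
#' `Inf` distance and are flagged.
#'
#' @param graph filtered igraph.
#' @param signature_genes,target_genes character vectors.
#' @return data.frame: `signature_gene`, `nearest_target`, `distance`,
#'   `path` (pipe-joined nodes), `in_graph`.
#' @export
proximity <- function(graph, signature_genes, target_genes) {
  nodes <- igraph::V(graph)$name
  tg <- sort(intersect(target_genes, nodes))
  out <- data.frame(signature_gene = signature_genes,
                    nearest_target = NA_character_, distance = Inf,
                    path = NA_character_,
                    in_graph = signature_genes %in% nodes,
                    stringsAsFactors = FALSE)
  sg <- signature_genes[out$in_graph]
  if (length(sg) && length(tg)) {
    d <- igraph::distances(graph, v = sg, to = tg, weights = NA)
    for (i in seq_along(sg)) {
      row <- d[i, ]
      if (all(is.infinite(row))) next
      j <- which(row == min(row))[1]  # tg sorted, so first = smallest id
      ri <- which(out$signature_gene == sg[i])
      out$distance[ri] <- row[j]
      out$nearest_target[ri] <- tg[j]
      sp <- igraph::shortest_paths(graph, from = sg[i], to = tg[j],
                                   weights = NA)$vpath[[1]]
      out$path[ri] <- paste(names(sp), collapse = "|")
    }
  }
  out
}

#' Extract the signature-target subgraph
#'
#' Induced subgraph on the union of signature genes and drug targets present
#' in the filtered graph; nodes with no surviving incident edge are dropped.
#' Each remaining node is classed `signature`, `target`, or `both`.
#'
#' @param graph filtered igraph.
#' @param signature_genes,target_genes character vectors.
#' @return list with `graph` (igraph) and `nodes` (data.frame `gene`,
#'   `class`).
#' @export
extract_subgraph <- function(graph, signature_genes, target_genes) {
  keep <- intersect(union(signature_genes, target_genes),
                    igraph::V(graph)$name)
  sub <- igraph::induced_subgraph(graph, keep)
  deg <- igraph::degree(sub)
  sub <- igraph::delete_vertices(sub, names(deg)[deg == 0])
  nm <- igraph::V(sub)$name
  cls <- ifelse(nm %in% signature_genes & nm %in% target_genes, "both",
                ifelse(nm %in% signature_genes, "signature", "target"))
  list(graph = sub,
       nodes = data.frame(gene = nm, class = cls, stringsAsFactors = FALSE))
}

#' Select validation candidate genes
#'
#' Up-regulated signature genes directly connected (distance 1) to a drug
#' target in the filtered network, ordered literature-unknown genes first
#' (then by gene id) and truncated to `k`. Fewer than `k` eligible genes
#' returns them all with a warning.
#'
#' @param up_signature up-regulated signature genes.
#' @param proximity_table result of [proximity()].
#' @param known_flags character vector of literature-known genes (an input
#'   annotation, not computed).
#' @param k list length (default 10).
#' @return character vector of candidate genes.
#' @export
select_validation_candidates <- function(up_signature, proximity_table,
                                         known_flags = character(0), k = 10) {
  tab <- proximity_table[proximity_table$signature_gene %in% up_signature &
                           proximity_table$distance == 1, , drop = FALSE]
  if (!nrow(tab)) {
    warning("no up-regulated signature gene is directly connected to a target")
    return(character(0))
  }
  known <- tab$signature_gene %in% known_flags
  ord <- order(tab$distance, known, tab$signature_gene)
  cand <- tab$signature_gene[ord]
  if (length(cand) < k)
    warning("only ", length(cand), " eligible candidate(s) (k = ", k, ")")
  utils::head(cand, k)
}
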