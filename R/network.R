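## ceRNA network construction: miRNA-circRNA edges come from decoy
## prediction, miRNA-mRNA edges from cleavage-competent target prediction.
## The graph is tripartite in node type but bipartite in edges (miRNAs in
## the middle); circRNA-mRNA and same-type edges never occur.

#' Predict miRNA targets among mRNA sequences
#'
#' Reuses the duplex aligner with cleavage-competent criteria: perfect seed
#' (positions 2-8), at most 2 central defects (positions 9-20) and at most
#' 4 defects elsewhere.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param mrna_seqs named character vector of mRNA sequences.
#' @param min_score minimum duplex score.
#' @param max_central maximum central defects for a cleavable target site.
#' @return data.frame of edges: `mirna_id`, `mrna_id`, `score`.
#' @export
predict_mrna_targets <- function(mirnas, mrna_seqs,
                                 min_score = DECOY_SCORING$min_score,
                                 max_central = 2L) {
  rows <- list()
  for (mid in names(mirnas)) {
    for (gid in names(mrna_seqs)) {
      sites <- duplex_align(mirnas[[mid]], normalize_rna(mrna_seqs[[gid]]),
                            min_score = min_score)
      for (s in sites) {
        rc <- s$counts
        if (rc[["seed"]] == 0L && rc[["central"]] <= max_central &&
            rc[["other"]] <= 4L) {
          rows[[length(rows) + 1L]] <- data.frame(mirna_id = mid,
            mrna_id = gid, score = s$score, stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(mirna_id = character(0), mrna_id = character(0),
                  score = numeric(0))
}

#' Build a circRNA-miRNA-mRNA (ceRNA) network
#'
#' @param decoy_hits data.frame with `mirna_id`, `circ_id` (and optionally
#'   `score`), e.g. the `hits` table of [predict_decoys()].
#' @param target_edges data.frame with `mirna_id`, `mrna_id` (and
#'   optionally `score`) from [predict_mrna_targets()].
#' @return an undirected `igraph` with vertex attribute `type` in
#'   `{"miRNA", "circRNA", "mRNA"}` and edge attribute `score`.
#' @export
build_network <- function(decoy_hits, target_edges) {
  e1 <- if (nrow(decoy_hits))
    data.frame(from = decoy_hits$mirna_id, to = decoy_hits$circ_id,
               score = decoy_hits$score %||% rep(NA_real_, nrow(decoy_hits)),
               to_type = "circRNA", stringsAsFactors = FALSE)
  else NULL
  e2 <- if (nrow(target_edges))
    data.frame(from = target_edges$mirna_id, to = target_edges$mrna_id,
               score = target_edges$score %||% rep(NA_real_, nrow(target_edges)),
               to_type = "mRNA", stringsAsFactors = FALSE)
  else NULL
  edges <- rbind(e1, e2)
  if (is.null(edges) || nrow(edges) == 0)
    return(igraph::make_empty_graph(directed = FALSE))
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  verts <- rbind(data.frame(name = unique(edges$from), type = "miRNA",
                            stringsAsFactors = FALSE),
                 data.frame(name = unique(edges$to[edges$to_type == "circRNA"]),
                            type = "circRNA", stringsAsFactors = FALSE),
                 data.frame(name = unique(edges$to[edges$to_type == "mRNA"]),
                            type = "mRNA", stringsAsFactors = FALSE))
  if (anyDuplicated(verts$name))
    stop_fmt("node id used with more than one type: %s",
             paste(verts$name[duplicated(verts$name)], collapse = ", "))
  igraph::graph_from_data_frame(edges[, c("from", "to", "score")],
                                directed = FALSE, vertices = verts)
}

#' Connected components of a ceRNA network
#'
#' @param network an igraph from [build_network()].
#' @return list with `membership` (named vector), `sizes` (component
#'   sizes) and `histogram` (table of components by size).
#' @export
network_components <- function(network) {
  comp <- igraph::components(network)
  list(membership = comp$membership, sizes = comp$csize,
       histogram = table(comp$csize))
}

#' Export a ceRNA network
#'
#' @param network an igraph from [build_network()].
#' @param path output path.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @export
export_network <- function(network, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    types <- igraph::vertex_attr(network, "type")
    names(types) <- igraph::V(network)$name
    if (format == "sif") {
      rel <- ifelse(types[el[, 2]] == "circRNA" | types[el[, 1]] == "circRNA",
                    "decoy", "target")
      writeLines(if (nrow(el)) sprintf("%s\t%s\t%s", el[, 1], rel, el[, 2])
                 else character(0), path)
    } else {
      df <- data.frame(from = el[, 1], from_type = unname(types[el[, 1]]),
                       to = el[, 2], to_type = unname(types[el[, 2]]))
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Import a GraphML ceRNA network
#'
#' @param path a GraphML file written by [export_network()].
#' @return an igraph.
#' @export
import_network <- function(path) igraph::read_graph(path, format = "graphml")
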