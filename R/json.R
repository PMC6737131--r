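#' Write a pathway graph as JSON
#'
#' Plain JSON serialisation of a [pathway_graph()] (compound list plus one
#' object per edge), used by the command-line interface to pass graphs
#' between steps. [read_pathway_json()] is the exact inverse.
#'
#' @param graph A [pathway_graph()].
#' @param path Output file path.
#' @export
write_pathway_json <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  e <- graph$edges
  edges <- lapply(seq_len(nrow(e)), function(k) {
    list(i = e$i[k], j = e$j[k], reaction_id = e$reaction_id[k],
         score = e$score[k],
         locus_tags = as.list(e$locus_tags[[k]]),
         ko_ids = as.list(e$ko_ids[[k]]))
  })
  jsonlite::write_json(list(compounds = as.list(graph$compounds),
                            edges = edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pathway graph from JSON
#'
#' @param path A file written by [write_pathway_json()].
#' @return A [pathway_graph()].
#' @export
read_pathway_json <- function(path) {
  x <- jsonlite::read_json(path)
  edges <- NULL
  if (length(x$edges) > 0L) {
    edges <- data.frame(
      i = vapply(x$edges, function(e) as.integer(e$i), integer(1)),
      j = vapply(x$edges, function(e) as.integer(e$j), integer(1)),
      reaction_id = vapply(x$edges, function(e) e$reaction_id, character(1)),
      score = vapply(x$edges, function(e) as.integer(e$score), integer(1)),
      stringsAsFactors = FALSE)
    edges$locus_tags <- lapply(x$edges, function(e)
      as.character(unlist(e$locus_tags)))
    edges$ko_ids <- lapply(x$edges, function(e)
      as.character(unlist(e$ko_ids)))
  }
  pathway_graph(unlist(x$compounds), edges)
}

#' Write a remap result as JSON
#'
#' Serialises a [find_missing_egs()] result for the command line: missing
#' edges as compound-id pairs with reaction identifiers, missing genes,
#' propagated edges, and the S' matrix in sparse triplet form.
#'
#' @param result A \code{remap_result}.
#' @param graph The [pathway_graph()] it was computed from.
#' @param path Output file path.
#' @export
write_remap_json <- function(result, graph, path) {
  stopifnot(inherits(result, "remap_result"))
  edge_obj <- function(k) {
    e <- graph$edges[k, ]
    list(compound_i = graph$compounds[e$i], compound_j = graph$compounds[e$j],
         reaction_id = e$reaction_id, locus_tags = as.list(e$locus_tags[[1]]))
  }
  sp <- result$s_prime
  nz <- which(sp != 0 & upper.tri(sp), arr.ind = TRUE)
  triplets <- lapply(seq_len(nrow(nz)), function(r) {
    list(compound_i = rownames(sp)[nz[r, 1]],
         compound_j = colnames(sp)[nz[r, 2]],
         value = sp[nz[r, 1], nz[r, 2]])
  })
  jsonlite::write_json(
    list(missing_edges = lapply(result$missing_edges, edge_obj),
         missing_genes = as.list(result$missing_genes),
         propagated_edges = lapply(result$propagated_edges, edge_obj),
         s_prime = triplets),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
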