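#' Depth-first essential section around one edge
#'
#' Starting from one edge of the pathway graph, searches outward from both of
#' its endpoints under the traversal rule of the remapping algorithm: a new
#' edge, entered from one of its endpoints, is crossed (search continues
#' through its far endpoint) if the edge itself is essential (score 5) or if
#' at least one essential edge touches the far endpoint; an edge that is
#' non-essential with no essential edge at its far endpoint is still recorded
#' as reached, but the search stops there. A visited-edge set prevents
#' revisits within each side's search; the two sides are searched
#' independently, so an edge reachable from both endpoints counts for both.
#'
#' @param graph A [pathway_graph()].
#' @param start_edge Integer index of the start edge in \code{graph$edges}.
#' @param incidence Optional precomputed incidence list (internal reuse).
#' @return A list of class \code{essential_section}: \code{start_edge},
#'   \code{reached_edges} (sorted edge indices, start included),
#'   \code{side_edges} (edges reached from each endpoint, start excluded),
#'   and \code{side_has_eg} (two logicals: whether an essential edge is
#'   reachable from each endpoint, judged on the original scores).
#' @export
dfs_essential_section <- function(graph, start_edge, incidence = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  e <- graph$edges
  start_edge <- as.integer(start_edge)
  if (start_edge < 1L || start_edge > nrow(e)) .stopf("start_edge out of range")
  inc <- incidence %||% .incidence(graph)
  score <- e$score
  # an essential edge touches this compound?
  node_has_eg <- vapply(inc, function(idx) any(score[idx] == 5L), logical(1))

  search_side <- function(from_node) {
    visited <- logical(nrow(e))
    visited[start_edge] <- TRUE
    reached <- integer(0)
    stack <- from_node
    while (length(stack) > 0L) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (k in inc[[u]]) {
        if (visited[k]) next
        visited[k] <- TRUE
        reached <- c(reached, k)
        v <- if (e$i[k] == u) e$j[k] else e$i[k]
        if (score[k] == 5L || node_has_eg[v]) stack <- c(stack, v)
      }
    }
    reached
  }

  side <- list(search_side(e$i[start_edge]), search_side(e$j[start_edge]))
  structure(list(
    start_edge = start_edge,
    reached_edges = sort(unique(c(start_edge, side[[1]], side[[2]]))),
    side_edges = side,
    side_has_eg = c(any(score[side[[1]]] == 5L), any(score[side[[2]]] == 5L))
  ), class = "essential_section")
}

#' Rescore every edge by its essential section
#'
#' Produces the updated score matrix S': for each edge, the sum of the
#' original scores of all edges in its essential section (the start edge's
#' own score included). Compound pairs with no reaction stay 0; parallel
#' edges collapse by the maximum section sum, as in [reaction_matrix()].
#'
#' @param graph A [pathway_graph()].
#' @return Symmetric integer matrix of section score sums, with compound
#'   identifiers as dimnames.
#' @export
rescore <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  e <- graph$edges
  inc <- .incidence(graph)
  Sp <- matrix(0L, graph$n, graph$n,
               dimnames = list(graph$compounds, graph$compounds))
  for (k in seq_len(nrow(e))) {
    sec <- dfs_essential_section(graph, k, incidence = inc)
    tot <- sum(e$score[sec$reached_edges])
    i <- e$i[k]; j <- e$j[k]
    Sp[i, j] <- max(Sp[i, j], tot)
    Sp[j, i] <- Sp[i, j]
  }
  Sp
}

#' Identify missing essential genes (gap genes) in one pathway map
#'
#' Single-pass remapping: every non-essential edge whose essential section
#' reaches an experimentally essential edge from \emph{both} of its endpoints
#' is reclassified as a missing essential gene — a reaction whose function is
#' essential but whose single-gene knockout was rescued by a paralog, isozyme
#' or alternative pathway. All sections are evaluated against the original
#' scores; reclassification never feeds back into the traversal (one gene can
#' appear on many edges of a map, so iterating to a fixed point could loop).
#' After the pass, gene-level propagation marks every other edge carrying a
#' reclassified gene as essential, once.
#'
#' @param graph A [pathway_graph()] built from labeled data.
#' @return A list of class \code{remap_result}: \code{missing_edges} (indices
#'   of reclassified edges), \code{missing_genes} (their locus tags, excluding
#'   tags already on an essential edge), \code{propagated_edges} (edges, not
#'   themselves essential or missing, sharing a gene with a missing edge),
#'   and \code{s_prime} (the rescored matrix from [rescore()]).
#' @export
find_missing_egs <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  e <- graph$edges
  inc <- .incidence(graph)

  missing <- integer(0)
  Sp <- matrix(0L, graph$n, graph$n,
               dimnames = list(graph$compounds, graph$compounds))
  for (k in seq_len(nrow(e))) {
    sec <- dfs_essential_section(graph, k, incidence = inc)
    tot <- sum(e$score[sec$reached_edges])
    Sp[e$i[k], e$j[k]] <- max(Sp[e$i[k], e$j[k]], tot)
    Sp[e$j[k], e$i[k]] <- Sp[e$i[k], e$j[k]]
    if (e$score[k] == 1L && all(sec$side_has_eg)) missing <- c(missing, k)
  }

  essential_tags <- unique(unlist(e$locus_tags[e$score == 5L]))
  missing_genes <- setdiff(unique(unlist(e$locus_tags[missing])),
                           essential_tags)

  gap_tags <- unique(unlist(e$locus_tags[missing]))
  propagated <- which(
    e$score != 5L & !(seq_len(nrow(e)) %in% missing) &
      vapply(e$locus_tags, function(t) any(t %in% gap_tags), logical(1)))

  structure(list(missing_edges = missing,
                 missing_genes = sort(missing_genes),
                 propagated_edges = propagated,
                 s_prime = Sp),
            class = "remap_result")
}

#' Run the full remapping pass on one strain's pathway map
#'
#' Convenience wrapper composing the per-edge depth-first sections, the S'
#' rescoring and the missing-gene identification into the single search pass
#' applied per strain. The result is deterministic for a fixed graph,
#' regardless of edge storage order.
#'
#' @param graph A [pathway_graph()].
#' @return A \code{remap_result}; see [find_missing_egs()].
#' @export
remap_strain <- function(graph) {
  find_missing_egs(graph)
}

#' @export
print.remap_result <- function(x, ...) {
  cat(sprintf(paste0("remap_result: %d missing-EG edge(s), %d gap gene(s), ",
                     "%d propagated edge(s)\n"),
              length(x$missing_edges), length(x$missing_genes),
              length(x$propagated_edges)))
  invisible(x)
}

#' Tabulate a remap result against its graph
#'
#' Expands the edge indices of a [find_missing_egs()] result into a readable
#' table of compound identifier pairs, reaction identifiers and locus tags.
#'
#' @param result A \code{remap_result}.
#' @param graph The [pathway_graph()] the result was computed from.
#' @return Data frame with columns \code{compound_i}, \code{compound_j},
#'   \code{reaction_id}, \code{status} (\code{missing} or \code{propagated})
#'   and \code{locus_tags} (\code{";"}-joined).
#' @export
remap_table <- function(result, graph) {
  stopifnot(inherits(result, "remap_result"), inherits(graph, "pathway_graph"))
  idx <- c(result$missing_edges, result$propagated_edges)
  status <- rep(c("missing", "propagated"),
                c(length(result$missing_edges), length(result$propagated_edges)))
  e <- graph$edges[idx, , drop = FALSE]
  data.frame(compound_i = graph$compounds[e$i],
             compound_j = graph$compounds[e$j],
             reaction_id = e$reaction_id,
             status = status,
             locus_tags = vapply(e$locus_tags, paste, character(1),
                                 collapse = ";"),
             stringsAsFactors = FALSE)
}
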