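#' Construct a pathway graph
#'
#' A pathway graph is the compound-level view of a metabolic map: nodes are
#' compounds, and every reaction contributes undirected edges between its
#' substrate and product compounds. Each edge carries the reaction identifier,
#' the KOs and locus tags of the catalysing genes, and an essentiality score —
#' 5 when at least one gene on the reaction is experimentally essential, 1
#' when all are non-essential. Parallel edges between the same compound pair
#' (e.g. both directions of a reversible reaction, or isozyme reactions) are
#' kept distinct; they only collapse (by maximum score) when the graph is
#' flattened to a [reaction_matrix()].
#'
#' @param compounds Character vector of unique compound identifiers; edge
#'   endpoints index into this vector (1-based).
#' @param edges Data frame with integer columns \code{i}, \code{j} (endpoint
#'   indices, \code{i != j}), character \code{reaction_id}, integer
#'   \code{score} (1 or 5), and list columns \code{locus_tags} and
#'   \code{ko_ids} (character vectors, possibly empty).
#' @return An object of class \code{pathway_graph}: a list with elements
#'   \code{compounds}, \code{edges} and \code{n}.
#' @export
pathway_graph <- function(compounds, edges) {
  compounds <- as.character(compounds)
  if (anyDuplicated(compounds)) .stopf("duplicate compound identifiers")
  n <- length(compounds)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(i = integer(), j = integer(),
                        reaction_id = character(), score = integer())
    edges$locus_tags <- list()
    edges$ko_ids <- list()
  }
  edges$i <- as.integer(edges$i)
  edges$j <- as.integer(edges$j)
  edges$score <- as.integer(edges$score)
  if (!all(edges$i >= 1L & edges$i <= n & edges$j >= 1L & edges$j <= n))
    .stopf("edge endpoint index out of range [1, %d]", n)
  if (any(edges$i == edges$j))
    .stopf("self-loop edges are not allowed (compound reacting with itself)")
  if (!all(edges$score %in% c(1L, 5L)))
    .stopf("edge scores must be 1 (non-essential) or 5 (essential)")
  if (is.null(edges$locus_tags)) edges$locus_tags <- rep(list(character()), nrow(edges))
  if (is.null(edges$ko_ids)) edges$ko_ids <- rep(list(character()), nrow(edges))
  rownames(edges) <- NULL
  structure(list(compounds = compounds, edges = edges, n = n),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph: %d compounds, %d edges (%d essential, %d non-essential)\n",
              x$n, nrow(x$edges), sum(x$edges$score == 5L),
              sum(x$edges$score == 1L)))
  invisible(x)
}

# Incidence list: for each compound index, the edge indices touching it,
# ordered by (other endpoint's compound id, reaction id) so traversal order
# is deterministic whatever the edge storage order.
.incidence <- function(graph) {
  e <- graph$edges
  inc <- vector("list", graph$n)
  for (v in seq_len(graph$n)) {
    idx <- which(e$i == v | e$j == v)
    if (length(idx) > 1L) {
      other <- ifelse(e$i[idx] == v, e$j[idx], e$i[idx])
      idx <- idx[order(graph$compounds[other], e$reaction_id[idx])]
    }
    inc[[v]] <- idx
  }
  inc
}

#' Flatten a pathway graph to its reaction score matrix
#'
#' Builds the symmetric n-by-n compound matrix S whose entry \code{S[i, j]}
#' records the existence and essentiality of a reaction between compounds i
#' and j: 5 for an essential reaction, 1 for a non-essential one, 0 where no
#' reaction exists. Parallel edges collapse by maximum score; the diagonal
#' is 0.
#'
#' @param graph A [pathway_graph()].
#' @return Integer matrix with compound identifiers as dimnames.
#' @export
reaction_matrix <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  S <- matrix(0L, graph$n, graph$n,
              dimnames = list(graph$compounds, graph$compounds))
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    i <- e$i[k]; j <- e$j[k]
    S[i, j] <- max(S[i, j], e$score[k])
    S[j, i] <- S[i, j]
  }
  S
}
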