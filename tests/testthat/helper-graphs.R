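# Test helpers: toy graph builders and an independent oracle for the
# both-sides missing-EG criterion.

# Build a small pathway graph from an edge list. `edges` is a list of
# c(i, j, score) triples; reaction ids, locus tags and KOs are generated
# (one gene per edge) unless `tags` (list of character vectors) is given.
toy_graph <- function(n, edges, tags = NULL) {
  m <- length(edges)
  df <- data.frame(
    i = vapply(edges, `[`, numeric(1), 1),
    j = vapply(edges, `[`, numeric(1), 2),
    reaction_id = sprintf("R%04d", seq_len(m)),
    score = vapply(edges, `[`, numeric(1), 3))
  df$locus_tags <- tags %||% as.list(sprintf("g%03d", seq_len(m)))
  df$ko_ids <- as.list(sprintf("K%05d", seq_len(m)))
  pathway_graph(sprintf("C%05d", seq_len(n)), df)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent oracle for the missing-EG criterion, derived from the
# traversal rules in closed form rather than by running a search: a side of
# a non-essential start edge reaches an essential edge iff the endpoint has
# an incident score-5 edge other than the start, or some neighbour through a
# non-start edge has any incident score-5 edge (the search can only continue
# past nodes that touch an essential edge, which already decides the side).
oracle_side_ok <- function(graph, k, endpoint) {
  e <- graph$edges
  others <- setdiff(which(e$i == endpoint | e$j == endpoint), k)
  if (any(e$score[others] == 5L)) return(TRUE)
  for (t in others) {
    x <- if (e$i[t] == endpoint) e$j[t] else e$i[t]
    if (any(e$score[e$i == x | e$j == x] == 5L)) return(TRUE)
  }
  FALSE
}

oracle_missing_edges <- function(graph) {
  e <- graph$edges
  cand <- which(e$score == 1L)
  cand[vapply(cand, function(k) {
    oracle_side_ok(graph, k, e$i[k]) && oracle_side_ok(graph, k, e$j[k])
  }, logical(1))]
}

# Fixed family of small topologies (node count, edge list without scores)
# over which score assignments are enumerated exhaustively.
enum_topologies <- function() {
  list(
    path4 = list(n = 4, ij = list(c(1, 2), c(2, 3), c(3, 4))),
    path6 = list(n = 6, ij = list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6))),
    cycle5 = list(n = 5, ij = list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1))),
    star5 = list(n = 5, ij = list(c(1, 2), c(1, 3), c(1, 4), c(1, 5))),
    theta = list(n = 4, ij = list(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                                  c(1, 3), c(1, 3))),      # parallel pair
    tree8 = list(n = 8, ij = list(c(1, 2), c(1, 3), c(2, 4), c(2, 5),
                                  c(3, 6), c(3, 7), c(6, 8), c(4, 8),
                                  c(5, 7), c(2, 7)))        # 10 edges, cycles
  )
}

# All graphs from one topology under every {1,5} score assignment.
enum_score_graphs <- function(topo) {
  m <- length(topo$ij)
  lapply(seq_len(2^m) - 1L, function(mask) {
    bits <- bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L)
    toy_graph(topo$n, mapply(function(ij, b) c(ij, if (b) 5 else 1),
                             topo$ij, bits, SIMPLIFY = FALSE))
  })
}

# Apply a permutation to a graph's edge storage order.
permute_edges <- function(graph, perm) {
  pathway_graph(graph$compounds, graph$edges[perm, , drop = FALSE])
}

# Canonical representation of an edge subset for order-independent
# comparison: sorted "cpd_i|cpd_j|reaction" keys.
edge_keys <- function(graph, idx) {
  e <- graph$edges[idx, , drop = FALSE]
  a <- pmin(graph$compounds[e$i], graph$compounds[e$j])
  b <- pmax(graph$compounds[e$i], graph$compounds[e$j])
  sort(paste(a, b, e$reaction_id, sep = "|"))
}

# Write a strain-gene or annotation fixture TSV from a character matrix.
write_fixture_tsv <- function(header, rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}
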