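#' Configuration for the synthetic fixture generators
#'
#' Bundles the parameters shared by [simulate_pathway()],
#' [simulate_strain_panel()] and [simulate_annotations()]. Defaults emulate a
#' small metabolic map and a DEG-style training panel of 31 strains — the
#' panel size of the training set the scoring system is calibrated on.
#'
#' @param n_compounds Number of compounds (graph nodes).
#' @param n_reactions Number of reactions (graph edges), at least
#'   \code{n_compounds - 1} so the map can be connected.
#' @param n_strains Training strains in the panel (default 31).
#' @param essential_fraction Target fraction of reactions carrying an
#'   essential gene, in (0, 1).
#' @param n_paralog_pairs Paralog/isozyme gene pairs planted as recoverable
#'   gap edges (at most \code{n_reactions / 2}).
#' @param n_kos Size of the KO universe for panels and annotation tables.
#' @param seed Integer seed; every generator is deterministic given it.
#' @param p_present Per-strain Bernoulli probability that a KO appears in a
#'   strain's genome (default 1: present everywhere).
#' @param annotation_group_size Number of KOs sharing one annotation string
#'   in [simulate_annotations()].
#' @param n_seed_kos KOs given their own reaction identifiers (the tallied
#'   set) in [simulate_annotations()]; default a quarter of \code{n_kos}.
#' @param n_reaction_linked KOs wired to attach to the seed set through a
#'   shared reaction identifier via [expand_by_reaction()].
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(n_compounds = 20, n_reactions = 26, n_strains = 31,
                         essential_fraction = 0.4, n_paralog_pairs = 2,
                         n_kos = 60, seed = 1, p_present = 1,
                         annotation_group_size = 5,
                         n_seed_kos = NULL, n_reaction_linked = 0) {
  n_seed_kos <- n_seed_kos %||% max(1L, n_kos %/% 4L)
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_reactions = as.integer(n_reactions),
              n_strains = as.integer(n_strains),
              essential_fraction = essential_fraction,
              n_paralog_pairs = as.integer(n_paralog_pairs),
              n_kos = as.integer(n_kos),
              seed = as.integer(seed),
              p_present = p_present,
              annotation_group_size = as.integer(annotation_group_size),
              n_seed_kos = as.integer(n_seed_kos),
              n_reaction_linked = as.integer(n_reaction_linked))
  if (cfg$n_compounds < 4L) .stopf("n_compounds must be >= 4")
  if (cfg$n_reactions < cfg$n_compounds - 1L)
    .stopf("n_reactions must be >= n_compounds - 1 for a connected map")
  if (!(essential_fraction > 0 && essential_fraction < 1))
    .stopf("essential_fraction must lie in (0, 1)")
  if (cfg$n_paralog_pairs > cfg$n_reactions %/% 2L)
    .stopf("n_paralog_pairs must be <= n_reactions / 2")
  if (cfg$n_strains < 1L) .stopf("n_strains must be >= 1")
  if (!(p_present > 0 && p_present <= 1))
    .stopf("p_present must lie in (0, 1]")
  if (cfg$n_seed_kos + cfg$n_reaction_linked > cfg$n_kos)
    .stopf("n_seed_kos + n_reaction_linked must be <= n_kos")
  structure(cfg, class = "synth_config")
}

# Random spanning tree over the node ids `nodes`: each node after the first
# attaches to a uniformly chosen earlier node.
.random_tree <- function(nodes) {
  m <- length(nodes)
  if (m < 2L) return(cbind(integer(0), integer(0)))
  parent <- vapply(2:m, function(k) nodes[sample.int(k - 1L, 1L)], integer(1))
  cbind(parent, nodes[2:m])
}

# Sample `k` distinct unordered node pairs from `nodes`, excluding the pairs
# in `used` (2-column matrix). Config error when not enough pairs exist.
.free_pairs <- function(nodes, k, used) {
  if (k == 0L) return(cbind(integer(0), integer(0)))
  all_pairs <- t(utils::combn(nodes, 2L))
  keyify <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  avail <- all_pairs[!(keyify(all_pairs) %in% keyify(used)), , drop = FALSE]
  if (nrow(avail) < k)
    .stopf("infeasible config: cannot place %d additional edge(s)", k)
  avail[sample.int(nrow(avail), k), , drop = FALSE]
}

#' Simulate a pathway map with planted gap genes
#'
#' Generates a connected random pathway graph with a known ground truth. The
#' map has two zones: an essential backbone (a random tree whose reactions
#' all carry an experimentally essential gene, score 5) and a non-essential
#' zone (a random tree of score-1 reactions, joined to the backbone by a
#' single score-1 bridge). Each paralog pair is planted as one score-1 gap
#' edge between two non-adjacent backbone compounds: its endpoints both touch
#' essential reactions, so the edge is guaranteed recoverable by the
#' both-sides remapping criterion, while its two genes are non-essential
#' (knocking out either is rescued by the other). Every other score-1 edge —
#' the bridge, the non-essential tree and any extra non-essential-zone edges
#' — violates the criterion by construction, so [remap_strain()] recovers
#' exactly the planted gaps.
#'
#' @param cfg A [synth_config()].
#' @return A list with elements \code{graph} (a [pathway_graph()]),
#'   \code{labels} (strain-gene style data frame of locus tag labels) and
#'   \code{truth}: \code{gap_edges} (edge indices in \code{graph$edges}),
#'   \code{paralog_pairs} (list of KO id pairs), \code{essential_kos},
#'   and \code{gap_kos}.
#' @export
simulate_pathway <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_compounds
  compounds <- sprintf("C%05d", seq_len(n))

  m_ess <- max(1L, round(cfg$essential_fraction * cfg$n_reactions))
  n_ess <- m_ess + 1L                      # essential tree nodes
  if (n_ess > n - 2L) n_ess <- n - 2L      # keep >= 2 nodes for the far zone
  if (n_ess < 3L && cfg$n_paralog_pairs > 0L)
    .stopf("infeasible config: essential zone too small to host gap edges")
  n_non <- n - n_ess

  ess_nodes <- seq_len(n_ess)
  non_nodes <- (n_ess + 1L):n

  ess_tree <- .random_tree(ess_nodes)                  # score 5
  non_tree <- .random_tree(non_nodes)                  # score 1
  bridge <- cbind(ess_nodes[sample.int(n_ess, 1L)], non_nodes[1L])  # score 1

  gaps <- .free_pairs(ess_nodes, cfg$n_paralog_pairs, ess_tree)

  n_extra <- cfg$n_reactions - nrow(ess_tree) - nrow(non_tree) - 1L -
    cfg$n_paralog_pairs
  if (n_extra < 0L)
    .stopf("infeasible config: n_reactions too small for %d paralog pair(s)",
           cfg$n_paralog_pairs)
  extra <- if (length(non_nodes) >= 3L) {
    .free_pairs(non_nodes, n_extra, rbind(non_tree, bridge))
  } else if (n_extra > 0L) {
    .stopf("infeasible config: no room for %d extra edge(s)", n_extra)
  } else cbind(integer(0), integer(0))

  ij <- rbind(ess_tree, gaps, bridge, non_tree, extra)
  score <- c(rep(5L, nrow(ess_tree)), rep(1L, nrow(ij) - nrow(ess_tree)))
  m <- nrow(ij)
  gap_rows <- nrow(ess_tree) + seq_len(cfg$n_paralog_pairs)

  # one reaction, one KO and one gene per edge; gap edges carry a paralog
  # pair: two genes with two KOs, both non-essential
  reaction_id <- sprintf("R%05d", seq_len(m))
  ko1 <- sprintf("K%05d", seq_len(m))
  ko2 <- sprintf("K%05d", m + seq_len(m))  # second KO slot (gap edges only)
  g1 <- sprintf("g%04d", seq_len(m))
  g2 <- sprintf("g%04d", m + seq_len(m))

  records <- data.frame(reaction_id = reaction_id, stringsAsFactors = FALSE)
  records$substrates <- lapply(ij[, 1], function(v) compounds[v])
  records$products <- lapply(ij[, 2], function(v) compounds[v])
  records$ko_ids <- lapply(seq_len(m), function(k)
    if (k %in% gap_rows) c(ko1[k], ko2[k]) else ko1[k])
  records$locus_tags <- lapply(seq_len(m), function(k)
    if (k %in% gap_rows) c(g1[k], g2[k]) else g1[k])
  attr(records, "compounds") <- compounds

  labels <- data.frame(
    locus_tag = c(g1, g2[gap_rows]),
    label = c(ifelse(score == 5L, "essential_experimental", "nonessential"),
              rep("nonessential", length(gap_rows))),
    stringsAsFactors = FALSE)

  graph <- build_pathway_graph(records, labels)

  list(graph = graph,
       labels = labels,
       records = records,
       truth = list(
         gap_edges = as.integer(gap_rows),
         paralog_pairs = lapply(gap_rows, function(k) c(ko1[k], ko2[k])),
         essential_kos = ko1[score == 5L],
         gap_kos = unique(unlist(lapply(gap_rows, function(k) c(ko1[k], ko2[k]))))
       ))
}

#' Simulate a multi-strain essentiality panel
#'
#' Generates DEG-style gene tables for \code{cfg$n_strains} strains over a
#' shared KO universe. Each KO is present in a strain with probability
#' \code{cfg$p_present} (independent Bernoulli draws; no phylogenetic
#' correlation is modelled) and, when present, is labeled experimentally
#' essential when it belongs to \code{essential_kos}. Expected per-KO tallies
#' are computed by direct bookkeeping on the presence draws, independently of
#' [tally_ko_essentiality()], so they can serve as an assertion target.
#'
#' @param cfg A [synth_config()].
#' @param essential_kos Character vector of KOs to label essential wherever
#'   present.
#' @return A list with \code{tables} (list of strain gene tables) and
#'   \code{expected_counts} (data frame with the same columns as
#'   [tally_ko_essentiality()] output).
#' @export
simulate_strain_panel <- function(cfg, essential_kos) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  kos <- sprintf("K%05d", seq_len(cfg$n_kos))
  ess <- kos %in% essential_kos
  present <- matrix(stats::runif(cfg$n_strains * cfg$n_kos) <= cfg$p_present,
                    nrow = cfg$n_strains)

  tables <- lapply(seq_len(cfg$n_strains), function(s) {
    sel <- which(present[s, ])
    data.frame(strain_id = sprintf("syn%02d", s),
               locus_tag = sprintf("syn%02d_g%04d", s, sel),
               ko_id = kos[sel],
               label = ifelse(ess[sel], "essential_experimental",
                              "nonessential"),
               stringsAsFactors = FALSE)
  })

  appearances <- as.integer(colSums(present))
  expected <- data.frame(ko_id = kos,
                         eg_e = ifelse(ess, appearances, 0L),
                         eg_m = 0L,
                         non_eg = ifelse(ess, 0L, appearances),
                         n_strains = cfg$n_strains,
                         stringsAsFactors = FALSE)
  expected <- expected[appearances > 0L, , drop = FALSE]
  rownames(expected) <- NULL
  list(tables = tables, expected_counts = expected)
}

#' Simulate a KO annotation table
#'
#' Generates annotations for \code{cfg$n_kos} KOs: KEGG-pathway annotation
#' strings assigned in blocks of \code{cfg$annotation_group_size} (the last
#' pathway block and an offset COG block are left empty, exercising the
#' empty-string group convention of [group_mean_score()]), COG strings
#' assigned in differently phased blocks, and reaction identifiers wired so
#' that exactly \code{cfg$n_reaction_linked} KOs beyond the
#' \code{cfg$n_seed_kos} seed KOs attach to the seed set under
#' [expand_by_reaction()].
#'
#' @param cfg A [synth_config()].
#' @return A KO annotation table in [read_ko_annotations()] layout.
#' @export
simulate_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  nk <- cfg$n_kos
  kos <- sprintf("K%05d", seq_len(nk))
  gs <- cfg$annotation_group_size

  path_grp <- (seq_len(nk) - 1L) %/% gs
  cog_grp <- (seq_len(nk) - 1L + gs %/% 2L) %/% gs
  path_ann <- sprintf("Pathway block %03d//Module %03d//",
                      path_grp, path_grp)
  cog_ann <- sprintf("COG family %03d//", cog_grp)
  path_ann[path_grp == max(path_grp)] <- ""     # empty-string pathway group
  cog_ann[cog_grp == min(cog_grp)] <- ""        # empty-string COG group

  rxn <- rep(list(character()), nk)
  n_seed <- cfg$n_seed_kos
  for (k in seq_len(n_seed)) rxn[[k]] <- sprintf("R%05d", k)
  if (cfg$n_reaction_linked > 0L) {
    linked <- n_seed + seq_len(cfg$n_reaction_linked)
    hosts <- sample.int(n_seed, cfg$n_reaction_linked, replace = TRUE)
    for (t in seq_along(linked)) rxn[[linked[t]]] <- sprintf("R%05d", hosts[t])
  }

  out <- data.frame(ko_id = kos,
                    kegg_pathway_annotation = path_ann,
                    cog_annotation = cog_ann,
                    stringsAsFactors = FALSE)
  out$reaction_ids <- rxn
  out$gene_name <- sprintf("gene%05d", seq_len(nk))
  out$description <- sprintf("synthetic ortholog %05d", seq_len(nk))
  out
}
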