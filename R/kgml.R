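#' Parse a KGML pathway file into reaction records
#'
#' Reads a KGML (KEGG Markup Language) XML file — a real ko01100-style map or
#' one written by [write_kgml()] — and extracts one record per
#' \code{<reaction>} element. Locus tags come from \code{<entry>} elements of
#' type \code{"gene"} whose \code{reaction} attribute names the reaction; KO
#' identifiers come from entries of type \code{"ortholog"} in the same way.
#' Entries of any other type contribute no locus tags, and reactions with no
#' resolvable gene entry are retained with an empty locus tag set (reference,
#' non-organism maps).
#'
#' @param path Path to a KGML XML file.
#' @return A data frame of reaction records with columns \code{reaction_id}
#'   and list columns \code{substrates}, \code{products}, \code{ko_ids},
#'   \code{locus_tags}. The full set of declared compound identifiers is
#'   attached as \code{attr(, "compounds")}.
#' @export
parse_kgml <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  doc <- xml2::read_xml(path)

  entries <- xml2::xml_find_all(doc, ".//entry")
  etype <- xml2::xml_attr(entries, "type")
  ename <- xml2::xml_attr(entries, "name")
  erxn  <- xml2::xml_attr(entries, "reaction")

  compounds <- unique(.strip_prefix(
    unlist(strsplit(ename[etype == "compound"], " ", fixed = TRUE))))

  # reaction name -> locus tags / KO ids, from gene and ortholog entries
  collect <- function(type) {
    map <- new.env(parent = emptyenv())
    sel <- which(etype == type & !is.na(erxn) & nzchar(erxn))
    for (k in sel) {
      tags <- .strip_prefix(unlist(strsplit(ename[k], " ", fixed = TRUE)))
      for (rn in .strip_prefix(unlist(strsplit(erxn[k], " ", fixed = TRUE)))) {
        map[[rn]] <- unique(c(map[[rn]] %||% character(), tags))
      }
    }
    map
  }
  gene_map <- collect("gene")
  ko_map <- collect("ortholog")

  rxns <- xml2::xml_find_all(doc, ".//reaction")
  recs <- lapply(rxns, function(rx) {
    rid <- .strip_prefix(strsplit(xml2::xml_attr(rx, "name"), " ",
                                  fixed = TRUE)[[1]][1])
    subs <- .strip_prefix(xml2::xml_attr(
      xml2::xml_find_all(rx, "./substrate"), "name"))
    prods <- .strip_prefix(xml2::xml_attr(
      xml2::xml_find_all(rx, "./product"), "name"))
    if (length(subs) == 0L || length(prods) == 0L)
      .stopf("reaction '%s' lacks a substrate or product", rid)
    undeclared <- setdiff(c(subs, prods), compounds)
    if (length(undeclared) > 0L)
      .stopf("reaction '%s' references undeclared compound(s): %s", rid,
             paste(undeclared, collapse = ", "))
    list(reaction_id = rid, substrates = subs, products = prods,
         ko_ids = ko_map[[rid]] %||% character(),
         locus_tags = gene_map[[rid]] %||% character())
  })

  out <- data.frame(
    reaction_id = vapply(recs, `[[`, character(1), "reaction_id"),
    stringsAsFactors = FALSE)
  out$substrates <- lapply(recs, `[[`, "substrates")
  out$products <- lapply(recs, `[[`, "products")
  out$ko_ids <- lapply(recs, `[[`, "ko_ids")
  out$locus_tags <- lapply(recs, `[[`, "locus_tags")
  attr(out, "compounds") <- compounds
  out
}

#' Build a pathway graph from reaction records and essentiality labels
#'
#' Scores each reaction from the experimental labels of its genes — 5 when at
#' least one gene is essential, 1 when all are non-essential — and expands it
#' into undirected compound-compound edges: a reaction with several substrates
#' and products contributes one edge per substrate-product pair, all sharing
#' the reaction's score and gene sets. Locus tags absent from \code{labels}
#' are treated as non-essential with a warning (DEG-style tables label
#' essentials exhaustively, so an unlabeled gene is a non-essential one).
#'
#' @param records Reaction records from [parse_kgml()], or a compatible data
#'   frame carrying a \code{compounds} attribute.
#' @param labels Either a named character vector mapping locus tag to label
#'   (\code{essential_experimental} / \code{nonessential}), or a strain gene
#'   table from [read_strain_genes()].
#' @return A [pathway_graph()].
#' @export
build_pathway_graph <- function(records, labels) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$locus_tag)
  }
  compounds <- attr(records, "compounds") %||%
    unique(unlist(c(records$substrates, records$products)))

  all_tags <- unique(unlist(records$locus_tags))
  unlabeled <- setdiff(all_tags, names(labels))
  if (length(unlabeled) > 0L)
    .warnf("%d locus tag(s) without a label treated as non-essential (e.g. %s)",
           length(unlabeled), paste(utils::head(unlabeled, 3L), collapse = ", "))

  rows <- vector("list", nrow(records))
  for (k in seq_len(nrow(records))) {
    tags <- records$locus_tags[[k]]
    essential <- any(labels[tags] == "essential_experimental", na.rm = TRUE)
    score <- if (essential) 5L else 1L
    pairs <- expand.grid(s = records$substrates[[k]],
                         p = records$products[[k]],
                         stringsAsFactors = FALSE)
    rows[[k]] <- data.frame(
      i = match(pairs$s, compounds), j = match(pairs$p, compounds),
      reaction_id = records$reaction_id[k], score = score,
      stringsAsFactors = FALSE)
    rows[[k]]$locus_tags <- rep(list(tags), nrow(pairs))
    rows[[k]]$ko_ids <- rep(list(records$ko_ids[[k]]), nrow(pairs))
  }
  edges <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
  pathway_graph(compounds, edges)
}

#' Write a pathway graph as KGML
#'
#' Serialises a [pathway_graph()] back to the KGML dialect read by
#' [parse_kgml()]: compound entries, gene and ortholog entries keyed to
#' reactions, and one \code{<reaction>} element per edge. Parsing the output
#' and rebuilding with the same label table reproduces the graph's topology,
#' scores, reaction identifiers, locus tags and KOs.
#'
#' @param graph A [pathway_graph()].
#' @param path Output file path.
#' @export
write_kgml <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  doc <- xml2::xml_new_root("pathway", name = "path:synthetic",
                            title = "synthetic pathway map")
  id <- 0L
  nid <- function() { id <<- id + 1L; as.character(id) }
  for (cpd in graph$compounds) {
    xml2::xml_add_child(doc, "entry", id = nid(),
                        name = paste0("cpd:", cpd), type = "compound")
  }
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    rn <- paste0("rn:", e$reaction_id[k])
    tags <- e$locus_tags[[k]]
    if (length(tags) > 0L)
      xml2::xml_add_child(doc, "entry", id = nid(),
                          name = paste(paste0("syn:", tags), collapse = " "),
                          type = "gene", reaction = rn)
    kos <- e$ko_ids[[k]]
    if (length(kos) > 0L)
      xml2::xml_add_child(doc, "entry", id = nid(),
                          name = paste(paste0("ko:", kos), collapse = " "),
                          type = "ortholog", reaction = rn)
    rx <- xml2::xml_add_child(doc, "reaction", id = nid(), name = rn,
                              type = "reversible")
    xml2::xml_add_child(rx, "substrate", id = as.character(e$i[k]),
                        name = paste0("cpd:", graph$compounds[e$i[k]]))
    xml2::xml_add_child(rx, "product", id = as.character(e$j[k]),
                        name = paste0("cpd:", graph$compounds[e$j[k]]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
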