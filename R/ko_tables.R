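#' Read a KO annotation table
#'
#' Loads a tab-separated table of KEGG Orthology (KO) annotations. Each row
#' describes one KO: its multi-pathway KEGG annotation string (pathways joined
#' with \code{"//"}), its COG annotation string, the set of KEGG reaction
#' identifiers (\code{#R} numbers) it participates in, and free-text gene
#' name / description fields. Annotation strings are stored verbatim: grouping
#' for P_score computation operates on the full string, so no tokenisation
#' happens at load time.
#'
#' @param path Path to a UTF-8 TSV file with header columns \code{ko_id},
#'   \code{kegg_pathway_annotation}, \code{cog_annotation},
#'   \code{reaction_ids} (\code{";"}-separated), \code{gene_name},
#'   \code{description}.
#' @return A data frame with one row per KO. \code{reaction_ids} is a list
#'   column of character vectors (duplicates removed); empty cells become
#'   empty strings or empty character vectors.
#' @seealso [write_ko_annotations()], [expand_by_reaction()]
#' @export
read_ko_annotations <- function(path) {
  req <- c("ko_id", "kegg_pathway_annotation", "cog_annotation",
           "reaction_ids", "gene_name", "description")
  df <- .read_tsv(path, req)
  df <- df[, req, drop = FALSE]
  if (anyDuplicated(df$ko_id))
    .stopf("duplicate ko_id in annotation table: %s",
           paste(unique(df$ko_id[duplicated(df$ko_id)]), collapse = ", "))
  bad <- df$ko_id[!.is_ko_id(df$ko_id)]
  if (length(bad) > 0L)
    .stopf("malformed ko_id (expected K + 5 digits): %s",
           paste(utils::head(bad, 5L), collapse = ", "))
  df$reaction_ids <- lapply(strsplit(df$reaction_ids, ";", fixed = TRUE),
                            function(r) unique(r[nzchar(r)]))
  rownames(df) <- NULL
  df
}

#' Write a KO annotation table
#'
#' Inverse of [read_ko_annotations()]; round-trips exactly.
#'
#' @param annotations Data frame as returned by [read_ko_annotations()].
#' @param path Output TSV path.
#' @export
write_ko_annotations <- function(annotations, path) {
  out <- annotations
  out$reaction_ids <- vapply(annotations$reaction_ids, paste,
                             character(1), collapse = ";")
  .write_tsv(out, path)
  invisible(path)
}

#' Read a strain gene table
#'
#' Loads the per-strain gene table linking locus tags to KO identifiers and
#' experimental essentiality labels (DEG-style: genome-wide single-knockout
#' calls, with essentials labeled exhaustively).
#'
#' @param path TSV with header columns \code{locus_tag}, \code{ko_id} (may be
#'   blank when no KO was assigned), \code{label} (one of
#'   \code{essential_experimental}, \code{nonessential}, \code{unknown}).
#' @param strain_id KEGG organism abbreviation recorded on every row.
#' @return Data frame with columns \code{strain_id}, \code{locus_tag},
#'   \code{ko_id} (\code{NA} when absent) and \code{label}.
#' @export
read_strain_genes <- function(path, strain_id) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L, nzchar(strain_id))
  df <- .read_tsv(path, c("locus_tag", "ko_id", "label"))
  if (anyDuplicated(df$locus_tag))
    .stopf("duplicate locus_tag in strain table '%s': %s", strain_id,
           paste(unique(df$locus_tag[duplicated(df$locus_tag)]), collapse = ", "))
  bad <- setdiff(unique(df$label), .eg_labels)
  if (length(bad) > 0L)
    .stopf("unknown essentiality label(s): %s (allowed: %s)",
           paste(bad, collapse = ", "), paste(.eg_labels, collapse = ", "))
  ko <- df$ko_id
  ko[!nzchar(ko)] <- NA_character_
  bad_ko <- ko[!is.na(ko) & !.is_ko_id(ko)]
  if (length(bad_ko) > 0L)
    .stopf("malformed ko_id in strain table '%s': %s", strain_id,
           paste(utils::head(bad_ko, 5L), collapse = ", "))
  data.frame(strain_id = strain_id, locus_tag = df$locus_tag,
             ko_id = ko, label = df$label, stringsAsFactors = FALSE)
}

#' Write a strain gene table
#'
#' Inverse of [read_strain_genes()] (the \code{strain_id} column is not
#' written; it is re-supplied at read time).
#'
#' @param genes Data frame as returned by [read_strain_genes()].
#' @param path Output TSV path.
#' @export
write_strain_genes <- function(genes, path) {
  out <- data.frame(locus_tag = genes$locus_tag,
                    ko_id = ifelse(is.na(genes$ko_id), "", genes$ko_id),
                    label = genes$label, stringsAsFactors = FALSE)
  .write_tsv(out, path)
  invisible(path)
}

#' Expand a KO set by shared reaction identifiers
#'
#' Single-hop expansion: adds every KO in the annotation table that shares at
#' least one reaction identifier (\code{#R}) with a member of \code{ko_set}.
#' The expansion is deliberately not a transitive closure — one pass attaches
#' KOs one shared-reaction hop away, mirroring how reaction linkage is used to
#' extend E_score coverage beyond the KOs seen in training strains.
#'
#' @param ko_set Character vector of KO identifiers. Members absent from the
#'   annotation table pass through unchanged.
#' @param annotations KO annotation table ([read_ko_annotations()]).
#' @return Character vector: \code{ko_set} plus all single-hop reaction-linked
#'   KOs (a superset of the input), sorted.
#' @export
expand_by_reaction <- function(ko_set, annotations) {
  ko_set <- unique(as.character(ko_set))
  idx <- match(ko_set, annotations$ko_id)
  seed_rxn <- unique(unlist(annotations$reaction_ids[idx[!is.na(idx)]]))
  if (length(seed_rxn) == 0L) return(sort(ko_set))
  hit <- vapply(annotations$reaction_ids,
                function(r) any(r %in% seed_rxn), logical(1))
  sort(unique(c(ko_set, annotations$ko_id[hit])))
}

#' Tally per-KO essentiality across training strains
#'
#' Summarises a panel of labeled strain gene tables into the per-KO counts
#' that feed [e_score()]: \code{eg_e} (strains where the KO is experimentally
#' essential), \code{eg_m} (strains where it is a missing essential — a gap
#' gene recovered by [remap_strain()]), and \code{non_eg} (strains where it
#' appears but is neither). Each strain contributes at most one unit to
#' exactly one tally per KO, with precedence experimental-essential >
#' missing-essential > non-essential when one KO maps to several genes with
#' mixed labels in a strain. Genes labeled \code{unknown} never enter tallies
#' (dropped with a warning).
#'
#' @param strain_tables List of strain gene tables ([read_strain_genes()]),
#'   one per training strain.
#' @param remapped Named list mapping \code{strain_id} to the character vector
#'   of locus tags that strain's remapping pass called missing essential.
#'   Tags must exist in the corresponding strain table.
#' @return Data frame with columns \code{ko_id}, \code{eg_e}, \code{eg_m},
#'   \code{non_eg}, \code{n_strains}, one row per KO observed in any strain.
#' @export
tally_ko_essentiality <- function(strain_tables, remapped = list()) {
  stopifnot(is.list(strain_tables), length(strain_tables) >= 1L)
  strain_ids <- vapply(strain_tables, function(t) t$strain_id[1], character(1))
  unknown_strains <- setdiff(names(remapped), strain_ids)
  if (length(unknown_strains) > 0L)
    .stopf("remapped refers to strain(s) not in the panel: %s",
           paste(unknown_strains, collapse = ", "))

  per_strain <- lapply(strain_tables, function(tab) {
    sid <- tab$strain_id[1]
    miss <- remapped[[sid]] %||% character()
    absent <- setdiff(miss, tab$locus_tag)
    if (length(absent) > 0L)
      .stopf("remapped locus tag(s) not found in strain '%s': %s", sid,
             paste(absent, collapse = ", "))
    if (any(tab$label == "unknown"))
      .warnf("strain '%s': %d gene(s) with unknown label dropped from tallies",
             sid, sum(tab$label == "unknown"))
    tab <- tab[!is.na(tab$ko_id) & tab$label != "unknown", , drop = FALSE]
    if (nrow(tab) == 0L)
      return(data.frame(ko_id = character(), class = character()))
    ess <- tapply(tab$label == "essential_experimental", tab$ko_id, any)
    mis <- tapply(tab$locus_tag %in% miss, tab$ko_id, any)
    cls <- ifelse(ess, "eg_e", ifelse(mis[names(ess)], "eg_m", "non_eg"))
    data.frame(ko_id = names(ess), class = unname(cls),
               stringsAsFactors = FALSE)
  })

  all <- do.call(rbind, per_strain)
  kos <- sort(unique(all$ko_id))
  count_of <- function(cl) {
    tab <- table(factor(all$ko_id[all$class == cl], levels = kos))
    as.integer(tab)
  }
  data.frame(ko_id = kos,
             eg_e = count_of("eg_e"),
             eg_m = count_of("eg_m"),
             non_eg = count_of("non_eg"),
             n_strains = length(strain_tables),
             stringsAsFactors = FALSE)
}
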