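#' Experimental essentiality score (E_score) for a KO
#'
#' Combines two aspects of a KO's behaviour across the training strains into
#' one score in \code{[0, 1)}:
#' \deqn{E = \left(\frac{EG_e + EG_m}{EG_e + EG_m + nonEG + 1}\right)^2
#'   \times \frac{EG_e + EG_m + nonEG}{N}}
#' The first factor is a shrunk estimate of how often the KO is essential
#' among the strains where it appears (the +1 in the denominator penalises
#' KOs seen in few strains); the second is the KO's appearance frequency.
#' With \code{n_strains = 31} the maximum attainable value is
#' \eqn{(31/32)^2 \approx 0.938}, reached by a KO essential in all strains.
#'
#' @param eg_e Strains where the KO is experimentally essential.
#' @param eg_m Strains where it is a missing essential (remapping gap gene).
#' @param non_eg Strains where it appears but is non-essential.
#' @param n_strains Total number of training strains (default 31).
#'   All arguments are vectorised.
#' @return Numeric vector of E_scores.
#' @export
e_score <- function(eg_e, eg_m = 0, non_eg = 0, n_strains = 31) {
  if (any(n_strains < 1)) .stopf("n_strains must be >= 1")
  if (any(eg_e < 0 | eg_m < 0 | non_eg < 0))
    .stopf("essentiality counts must be non-negative")
  if (any(eg_e + eg_m + non_eg > n_strains))
    .stopf("counts exceed the number of training strains")
  appear <- eg_e + eg_m + non_eg
  (( (eg_e + eg_m) / (appear + 1) )^2) * (appear / n_strains)
}

#' Annotation-group mean E_score for one KO
#'
#' The building block of P_score: the mean E_score of all KOs sharing the
#' same annotation string as \code{ko_id} (the KO itself excluded). Grouping
#' is exact full-string comparison on the \code{"//"}-joined annotation — the
#' empty string forms its own group, so KOs with no annotation under a key
#' still receive the mean of the other unannotated KOs. Returns 0 when no
#' group member has an E_score.
#'
#' @param ko_id KO identifier, present in \code{annotations}.
#' @param key \code{"kegg_pathway"} or \code{"cog"}: which annotation string
#'   defines the group.
#' @param annotations KO annotation table ([read_ko_annotations()]).
#' @param e_scores Named numeric vector of E_scores by KO id (KOs without an
#'   E_score may be absent or \code{NA}).
#' @return A single number in \code{[0, 1)}.
#' @export
group_mean_score <- function(ko_id, key = c("kegg_pathway", "cog"),
                             annotations, e_scores) {
  key <- match.arg(key)
  col <- if (key == "kegg_pathway") "kegg_pathway_annotation" else "cog_annotation"
  pos <- match(ko_id, annotations$ko_id)
  if (is.na(pos)) .stopf("KO '%s' not found in annotation table", ko_id)
  members <- annotations$ko_id[annotations[[col]] == annotations[[col]][pos]]
  members <- setdiff(members, ko_id)
  es <- e_scores[members]
  es <- es[!is.na(es)]
  if (length(es) == 0L) return(0)
  mean(es)
}

#' Combine P_score components
#'
#' Averages the KEGG-pathway and COG group scores into the final P_score.
#' \code{raw_mean} takes the plain arithmetic mean of the available
#' components (both already live on \code{[0, 1]}); \code{minmax_standardized}
#' first rescales each component to \code{[0, 1]} across all KOs by min-max
#' normalisation, then averages — available for sensitivity analysis via
#' [score_all()]. The result is absent (\code{NA}) only when both components
#' are absent, i.e. the KO has neither a KEGG pathway nor a COG annotation.
#'
#' @param p_kegg,p_cog Numeric vectors (possibly \code{NA}) of group scores.
#' @param mode Combination mode; at this level both modes average the values
#'   as given (the min-max rescaling is a population operation applied by
#'   [score_all()] before calling this).
#' @return Numeric vector of combined P_scores.
#' @export
p_score <- function(p_kegg, p_cog, mode = c("raw_mean", "minmax_standardized")) {
  mode <- match.arg(mode)
  both <- cbind(p_kegg, p_cog)
  out <- rowMeans(both, na.rm = TRUE)
  out[is.na(p_kegg) & is.na(p_cog)] <- NA_real_
  unname(out)
}

# Min-max rescale a vector to [0,1]; constant or empty vectors map to 0.
.minmax <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  rng <- range(x[ok])
  if (rng[1] == rng[2]) { x[ok] <- 0; return(x) }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Score every KO: E_score, P_score components, combined P_score
#'
#' Runs the full scoring pass over an annotation table and a per-KO
#' essentiality tally. E_scores are computed directly for every tallied KO;
#' a KO with no tally of its own but sharing a reaction identifier with
#' tallied KOs inherits the mean E_score of those reaction-link partners
#' (flagged \code{reaction_linked} in the output). P_score components are
#' computed for every KO with at least one annotation string, by exact-string
#' group means with self-exclusion; KOs with neither annotation get
#' \code{NA}.
#'
#' @param annotations KO annotation table ([read_ko_annotations()]).
#' @param tallies Tally table from [tally_ko_essentiality()].
#' @param mode Passed to [p_score()]; \code{"minmax_standardized"} min-max
#'   rescales each P component across KOs before averaging.
#' @param per_token If \code{TRUE}, annotation groups are formed by sharing
#'   at least one \code{"//"}-separated token instead of the whole string
#'   (sensitivity analysis; default exact full-string grouping).
#' @return Data frame with one row per KO in \code{annotations} (plus tallied
#'   KOs missing from it): \code{ko_id}, \code{e_score},
#'   \code{e_score_source} (\code{direct} / \code{reaction_linked} /
#'   \code{absent}), \code{p_score_kegg}, \code{p_score_cog}, \code{p_score}.
#'   A distribution summary of both scores is attached as
#'   \code{attr(, "summary")} (see [score_summary()]).
#' @export
score_all <- function(annotations, tallies,
                      mode = c("raw_mean", "minmax_standardized"),
                      per_token = FALSE) {
  mode <- match.arg(mode)
  kos <- union(annotations$ko_id, tallies$ko_id)

  es <- stats::setNames(rep(NA_real_, length(kos)), kos)
  src <- stats::setNames(rep("absent", length(kos)), kos)
  if (nrow(tallies) > 0L) {
    es[tallies$ko_id] <- e_score(tallies$eg_e, tallies$eg_m, tallies$non_eg,
                                 tallies$n_strains)
    src[tallies$ko_id] <- "direct"
  }

  # reaction-linked inheritance: untallied KOs sharing an #R with tallied KOs
  tallied_idx <- match(tallies$ko_id, annotations$ko_id)
  tallied_idx <- tallied_idx[!is.na(tallied_idx)]
  rxn2ko <- list()
  for (k in tallied_idx) {
    for (rn in annotations$reaction_ids[[k]])
      rxn2ko[[rn]] <- c(rxn2ko[[rn]], annotations$ko_id[k])
  }
  if (length(rxn2ko) > 0L) {
    for (k in seq_len(nrow(annotations))) {
      ko <- annotations$ko_id[k]
      if (src[ko] == "direct") next
      partners <- unique(unlist(rxn2ko[annotations$reaction_ids[[k]]]))
      partners <- setdiff(partners, ko)
      if (length(partners) > 0L) {
        es[ko] <- mean(es[partners])
        src[ko] <- "reaction_linked"
      }
    }
  }

  group_means <- function(strings) {
    # mean E_score per group with self-exclusion, exact-string groups
    ann_es <- es[annotations$ko_id]
    if (!per_token) {
      g <- factor(strings)
      has <- !is.na(ann_es)
      sums <- tapply(ifelse(has, ann_es, 0), g, sum)
      cnts <- tapply(has, g, sum)
      gi <- as.integer(g)
      num <- sums[gi] - ifelse(has, ann_es, 0)
      den <- cnts[gi] - as.integer(has)
      out <- ifelse(den > 0, num / den, 0)
      return(as.numeric(out))
    }
    toks <- strsplit(strings, "//", fixed = TRUE)
    toks <- lapply(seq_along(toks), function(k) {
      t <- toks[[k]][nzchar(toks[[k]])]
      if (length(t) == 0L) "" else t
    })
    vapply(seq_along(toks), function(k) {
      share <- vapply(toks, function(t) any(t %in% toks[[k]]), logical(1))
      share[k] <- FALSE
      v <- ann_es[share]
      v <- v[!is.na(v)]
      if (length(v) == 0L) 0 else mean(v)
    }, numeric(1))
  }

  pk <- group_means(annotations$kegg_pathway_annotation)
  pc <- group_means(annotations$cog_annotation)
  no_ann <- !nzchar(annotations$kegg_pathway_annotation) &
    !nzchar(annotations$cog_annotation)
  pk[no_ann] <- NA_real_
  pc[no_ann] <- NA_real_

  p_kegg <- stats::setNames(rep(NA_real_, length(kos)), kos)
  p_cog <- p_kegg
  p_kegg[annotations$ko_id] <- pk
  p_cog[annotations$ko_id] <- pc
  if (mode == "minmax_standardized") {
    p_kegg <- .minmax(p_kegg)
    p_cog <- .minmax(p_cog)
  }

  out <- data.frame(ko_id = kos,
                    e_score = unname(es),
                    e_score_source = unname(src),
                    p_score_kegg = unname(p_kegg),
                    p_score_cog = unname(p_cog),
                    p_score = p_score(unname(p_kegg), unname(p_cog), mode),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- score_summary(out)
  out
}

#' Distribution summary of a score table
#'
#' Minimum, maximum, mean, standard deviation and deciles of the E_score and
#' P_score columns of a [score_all()] result, over the KOs where each score
#' is present.
#'
#' @param scores A score table from [score_all()].
#' @return A list with elements \code{e_score} and \code{p_score}, each a
#'   named numeric vector of summary statistics.
#' @export
score_summary <- function(scores) {
  one <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L)
      return(c(n = 0, min = NA, max = NA, mean = NA, sd = NA))
    c(n = length(x), min = min(x), max = max(x), mean = mean(x),
      sd = stats::sd(x),
      stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9)))
  }
  list(e_score = one(scores$e_score), p_score = one(scores$p_score))
}
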