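---
title: "Predicting essential genes from pathway maps: the remapping and scoring model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting essential genes from pathway maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egpath)
```

## The problem

Genome-wide knockout screens label each gene of a prokaryote as essential or
non-essential, but a single-gene knockout misses essential *functions* that
are backed up by a paralog, an isozyme or an alternative pathway: deleting
either member of such a pair is survivable, so both genes are recorded
non-essential even though the function they share is indispensable. When
knockout labels from many training strains are pooled by KEGG Orthology (KO)
group to predict essentiality in unstudied organisms, these masked "gap
genes" systematically depress the pooled signal.

`egpath` implements a pathway-level remedy plus the scoring system built on
it:

1. **Remapping** — recover gap genes from the topology of a KEGG-style
   metabolic map (a ko01100-type global map encoded as KGML);
2. **E_score** — an experimental essentiality score per KO, pooled over a
   multi-strain training panel, with remapped gap genes counted as essential;
3. **P_score** — an annotation-group score that extends predictions to KOs
   never observed in the training panel;
4. threshold-based essentiality calls and confusion-matrix evaluation.

## The reaction matrix and the remapping search

Each reaction of a pathway map connects substrate and product compounds and
is catalysed by genes with known knockout labels. A reaction scores **5** if
at least one of its genes is essential and **1** if all are non-essential;
compound pairs with no reaction score 0. This gives the symmetric
compound-by-compound matrix **S** (`reaction_matrix()`), equivalently an
undirected multigraph whose nodes are compounds and whose edges are
reactions (`pathway_graph`). Edges are undirected: the search below speaks
only of "the node on the other end of the edge", never of reaction
direction, and reversible reactions that appear twice are kept as parallel
edges (they collapse by maximum score only in S).

From every edge, a depth-first search (`dfs_essential_section()`) explores
outward from both endpoints:

* the search **crosses** an edge if that edge is essential (score 5), or if
  at least one essential edge touches the node at its far end;
* the search **stops** at an edge that is non-essential with no essential
  edge at its far end — the edge is still recorded as reached, but nothing
  beyond it is.

The edges reached from one edge form its *essential section*. Summing the
original scores over the section (start edge included, so every existing
edge keeps a positive entry) gives the updated matrix **S′** (`rescore()`),
a per-edge diagnostic of how much essential signal surrounds the edge.

A non-essential edge is reclassified as a **missing essential gene** when
its section reaches an essential edge from *both* endpoints
(`find_missing_egs()`): the reaction sits on a through-route between
essential chemistry on either side, exactly the situation created by a
masked paralog pair. Two design points deserve emphasis:

* **The decision rule is the both-sides criterion, not a threshold on S′.**
  S′ is reported as a diagnostic, but no numeric cutoff on it is defined
  here; the both-sides criterion is the operational definition of a gap
  edge, and it is what the generator plants and the tests verify. A cutoff
  on S′ would be an invented parameter with no principled value.
* **The search runs once.** A gene can appear on many edges of a global
  map, so letting reclassified edges feed back into the traversal can cycle
  indefinitely; all sections are therefore evaluated against the original
  scores, and the gene-level propagation step (marking the other edges that
  carry a reclassified gene) is applied once, after the pass, without
  re-triggering any search. Re-running `remap_strain()` on the same graph
  reproduces the result exactly.

Side attribution on cycles: an edge reached from endpoint *u* belongs to
*u*'s side; the two sides are searched with independent visited sets, so an
edge reachable from both endpoints supports both. Traversal order is fixed
(incident edges sorted by far-compound id, then reaction id) purely so that
traces are reproducible — permutation tests assert the *results* never
depend on edge order.

## E_score

For KO *i* over *N* training strains (default *N* = 31, the panel size the
thresholds were calibrated on), with `EG_e` strains where the KO is
experimentally essential, `EG_m` strains where it is remapping-recovered
missing essential, and `nonEG` strains where it appears non-essential:

$$E_i = \left(\frac{EG_e + EG_m}{EG_e + EG_m + nonEG + 1}\right)^2
 \times \frac{EG_e + EG_m + nonEG}{N}$$

The first factor estimates the probability the KO is essential where it
appears, shrunk toward 0 by the +1 so that a KO seen essential in one strain
of one does not score 1; the second factor is appearance frequency, so
broadly conserved KOs outrank sporadic ones. The score lives in
\[0, (N/(N+1))²\]; at *N* = 31 the ceiling is (31/32)² ≈ 0.938, attained by
a KO present and essential in every strain, and the score is 0 exactly when
the KO is never essential anywhere. Each strain contributes one unit to one
tally per KO, with precedence experimental > missing > non-essential when a
KO maps to several genes with mixed labels in one strain (this mirrors the
"at least one gene essential" rule used at the reaction level; the training
data do not dictate a rule, so this is the package's choice).

KOs that never appear in the panel but share a reaction identifier (#R)
with tallied KOs inherit the mean E_score of their link partners, flagged
`reaction_linked` in `score_all()` output. The expansion is deliberately
single-hop, not a transitive closure — linkage is used once to extend
coverage, and the tests assert the single-hop semantics. Mean inheritance is
the least-surprising assignment for a KO whose only evidence is "catalyses
the same reaction"; the flag lets downstream users discount it.

## P_score

For annotation key *kegg_pathway* and *cog*, a KO's group is the set of KOs
whose full annotation string is byte-identical to its own (strings are
`"//"`-joined lists stored verbatim at load time). The group score is the
mean E_score of the other group members that have one, 0 if none does
(`group_mean_score()`). Exact full-string matching is the default because
the grouping a practitioner reads off an annotation table is the whole
string; per-token grouping (sharing any one pathway) is available as
`per_token = TRUE` for sensitivity analysis. The empty string is a group of
its own: KOs lacking, say, a COG annotation receive the mean E_score of the
other COG-less KOs, which is meaningful precisely because unannotated KOs
are a biased (mostly non-essential) population. A KO's own E_score is
excluded from its group mean so the operation is well defined for every KO,
scored or not.

P_score is the mean of the two components (`p_score()`); it is absent only
for KOs with neither annotation. The default combination is the raw mean —
both components already live on \[0, 1\], and the worked group-score
examples combine raw values — with min-max standardisation of each
component across KOs available as `mode = "minmax_standardized"`. Whether
the published 0.03 threshold presupposes standardisation is not decidable
from the description; thresholds here are plain configuration values, so a
user who standardises can re-threshold accordingly.

## Calls and evaluation

`predict_essentiality()` defaults to strict E-priority: when an E_score
exists the call is `e_score >= tau_e` (default 0.6) and P_score is ignored;
P_score decides (`p_score >= tau_p`, default 0.03) only when no E_score
exists. The rationale is that experimental evidence should outrank
annotation transfer; the alternative "essential if either score clears its
threshold" is available as `rule = "either"`, and rows where the two scores
disagree about their thresholds are flagged `score_conflict` for review.
Genes without a KO, or whose KO has no score of either kind, are `unscored`
and are excluded from evaluation, as are scored genes lacking an
experimental label. `classification_metrics()` reports sensitivity,
specificity, precision, accuracy and F-measure from the confusion matrix,
`NA` for any metric whose denominator is empty.

## The synthetic generators

`simulate_pathway()` builds maps with a known answer key. The construction
is two-zone: a random spanning tree of essential reactions (the essential
zone, sized by `essential_fraction`), a random tree of non-essential
reactions (the non-essential zone), one non-essential bridge edge joining
them, and any remaining edge budget spent inside the non-essential zone.
Each requested paralog pair becomes one non-essential *gap edge* between two
non-adjacent essential-zone compounds, carrying two genes (the pair) with
distinct KOs, both labeled non-essential. Because every essential-zone
compound touches an essential reaction, a gap edge satisfies the both-sides
criterion by construction; and because no non-essential-zone compound is
within reach of essential chemistry except across the bridge's far end,
every other non-essential edge violates it. Recovery is therefore exact by
design, and the test suite re-verifies both directions with a brute-force
oracle that is independent of the search implementation (a closed-form
radius-2 characterisation derived from the traversal rules: the search can
only continue past nodes that already touch an essential edge, so a side is
supported if and only if the endpoint or one of its non-start neighbours
touches one).

What the generator does **not** emulate: the degree distribution and
modular structure of real global metabolic maps, currency metabolites,
multi-substrate reactions (the generator emits one substrate and product
per reaction, although the parser and graph builder handle the general
case), genes recurring on many edges (exercised by hand-built fixtures
instead), and phylogenetic correlation between strains —
`simulate_strain_panel()` draws KO presence as independent Bernoulli trials
(`p_present`, default 1). Passing tests therefore demonstrate correctness
of the algorithms under their stated rules, not performance on real
genomes, which depends on map curation and label quality.

Default generator sizes (20 compounds, 26 reactions, 2 paralog pairs, 31
strains; 100 seeds in the recovery property) are chosen so the full suite
exercises trees, cycles, parallel edges and both empty-group conventions
while remaining a desk-scale object a reviewer can enumerate by eye.

## Numerical and degenerate-input choices

* Edge endpoints are 1-based indices into the compound vector (idiomatic
  R); all reports and serialisations use compound identifiers, never
  indices.
* Scores are stored at full precision; reports round E/P scores to 3
  decimals and metrics to 2, matching the precision such tables are printed
  at.
* A reaction with no genes at all scores 1 (nothing essential on it);
  locus tags missing from the label table are treated as non-essential with
  a warning, since knockout tables label essentials exhaustively.
* Genes labeled `unknown` never enter tallies (dropped with a warning);
  blank KO fields become missing values, and such genes are `unscored` at
  prediction time.
* Empty graphs, edgeless maps, header-only tables and all-zero confusion
  matrices are legal inputs with defined outputs (zero matrices, empty
  results, `NA` metrics) rather than errors.

## Known limitations

* The remapping criterion is purely topological; it cannot distinguish a
  masked paralog from a reaction that is simply flanked by essential
  chemistry for other reasons, and on real maps it is known to over-call in
  nutrient-replete conditions (media supplying an essential compound make
  the biosynthetic route non-essential experimentally but not
  topologically).
* E_score inherits every bias of the training panel: strain selection, KO
  assignment quality, and growth conditions.
* P_score transfers essentiality along annotation strings; its empty-string
  groups are informative but crude, and a KO with an idiosyncratic
  annotation string matches nobody under exact-string grouping.
* One map per remapping call; joint remapping across several maps of one
  organism is out of scope.
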