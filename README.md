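# egpath

Essential-gene prediction for prokaryotes from KEGG Orthology (KO)
annotations, multi-strain knockout panels, and metabolic pathway topology.

## The problem

Single-gene knockout screens miss essential *functions* that are backed up
by a paralog, an isozyme or an alternative pathway: either gene of such a
pair can be deleted alone, so both are recorded non-essential. When knockout
labels from many training strains are pooled per KO to predict essentiality
in unstudied organisms, these masked "gap genes" depress the signal.
`egpath` is for microbiologists and bioinformaticians who want
essentiality predictions (or training features) for organisms that have KO
annotations but no knockout data.

## The method

**Remapping.** A KGML pathway map becomes an undirected compound graph whose
edges are reactions, scored 5 when at least one catalysing gene is
experimentally essential and 1 otherwise (the reaction matrix *S*). From
each edge, a depth-first search crosses a neighbouring edge iff that edge is
essential or an essential edge touches its far endpoint, and stops
otherwise; the reached edges form the edge's *essential section*, whose
score sum gives the updated matrix *S′*. A non-essential edge whose section
reaches essential edges from **both** of its endpoints is reclassified as a
missing essential gene. The search runs once — reclassification never feeds
back into traversal — and a gene reclassified anywhere marks its other
edges once, by propagation.

**E_score.** Per KO over *N* training strains (default 31):

    E = ((EG_e + EG_m) / (EG_e + EG_m + nonEG + 1))^2 × (EG_e + EG_m + nonEG) / N

where `EG_e`, `EG_m`, `nonEG` count strains in which the KO is
experimentally essential, remapping-recovered missing essential, and
non-essential. Range 0 to (N/(N+1))² — 0.938 at N = 31.

**P_score.** For KOs without experimental evidence: the mean E_score of the
KOs sharing the same full KEGG-pathway annotation string, likewise for the
COG string (the empty string is a group of its own), averaged. Calls are
threshold-based with E-priority: `e_score >= 0.6` when available, else
`p_score >= 0.03`. Evaluation reports sensitivity, specificity, precision,
accuracy and F-measure.

All stages run on synthetic fixtures — seeded generators for pathway maps
with planted paralog gaps, strain panels and annotation tables — so the
whole pipeline is testable offline.

## Worked example

```r
library(egpath)

cfg <- synth_config(seed = 42)          # 20 compounds, 26 reactions,
sim <- simulate_pathway(cfg)            # 2 planted paralog gap edges
sim$graph
#> pathway_graph: 20 compounds, 26 edges (10 essential, 16 non-essential)

res <- remap_strain(sim$graph)
res
#> remap_result: 2 missing-EG edge(s), 4 gap gene(s), 0 propagated edge(s)
remap_table(res, sim$graph)
#>   compound_i compound_j reaction_id  status  locus_tags
#> 1     C00008     C00009      R00011 missing g0011;g0037
#> 2     C00004     C00011      R00012 missing g0012;g0038
```

The two recovered edges are exactly the planted paralog pairs: reactions
whose two redundant genes are individually dispensable but whose function
sits between essential chemistry on both sides. Feeding the gap genes back
into the tally as missing essential and scoring:

```r
panel <- simulate_strain_panel(cfg, sim$truth$essential_kos)
remapped <- setNames(lapply(panel$tables, function(tab)
    tab$locus_tag[tab$ko_id %in% sim$truth$gap_kos]),
  vapply(panel$tables, function(t) t$strain_id[1], character(1)))
tallies <- tally_ko_essentiality(panel$tables, remapped)
scores <- score_all(simulate_annotations(cfg), tallies)
head(scores[order(-scores$e_score), ], 1)
#>    ko_id   e_score e_score_source p_score_kegg p_score_cog   p_score
#> 1 K00001 0.9384766         direct    0.9384766   0.9384766 0.9384766
```

A KO essential in all 31 strains scores (31/32)² ≈ 0.938, the E_score
ceiling. Evaluating threshold calls against one strain's experimental
labels:

```r
pred <- predict_essentiality(scores, panel$tables[[1]])
cm <- confusion_matrix(pred, panel$tables[[1]])
cm
#> confusion: TP=10 FN=0 TN=46 FP=4 (n=60)
round(classification_metrics(cm), 2)
#> sensitivity specificity   precision    accuracy   f_measure
#>        1.00        0.92        0.71        0.93        0.83
```

The four "false positives" are the four paralog gap genes themselves:
experimentally non-essential (each is rescued by its partner), but called
essential because their *function* is — which is precisely the distinction
the remapping step exists to surface.

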