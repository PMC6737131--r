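test_that("KO annotation tables load verbatim and round-trip", {
  header <- c("ko_id", "kegg_pathway_annotation", "cog_annotation",
              "reaction_ids", "gene_name", "description")
  path <- write_fixture_tsv(header, list(
    c("K15792", "Lysine biosynthesis//Peptidoglycan biosynthesis//",
      paste0("UDP-N-acetylmuramyl tripeptide synthase//",
             "UDP-N-acetylmuramyl pentapeptide synthase//"), "", "", ""),
    c("K01928", "Lysine biosynthesis//Peptidoglycan biosynthesis//",
      "Other COG//", "R00001;R00002", "murE", "ligase")))
  ann <- read_ko_annotations(path)

  expect_equal(nrow(ann), 2L)
  expect_equal(ann$kegg_pathway_annotation[1],
               "Lysine biosynthesis//Peptidoglycan biosynthesis//")
  expect_equal(ann$reaction_ids[[1]], character(0))
  expect_setequal(ann$reaction_ids[[2]], c("R00001", "R00002"))
  expect_equal(ann$gene_name[1], "")

  out <- tempfile(fileext = ".tsv")
  write_ko_annotations(ann, out)
  expect_identical(read_ko_annotations(out), ann)
})

test_that("annotation loading enforces format and integrity", {
  header <- c("ko_id", "kegg_pathway_annotation", "cog_annotation",
              "reaction_ids", "gene_name", "description")
  empty <- write_fixture_tsv(header, list())
  expect_equal(nrow(read_ko_annotations(empty)), 0L)

  dup <- write_fixture_tsv(header, list(
    c("K00001", "A//", "", "", "", ""),
    c("K00001", "B//", "", "", "", "")))
  expect_error(read_ko_annotations(dup), "duplicate ko_id")

  short <- write_fixture_tsv(c("ko_id", "gene_name"), list(c("K00001", "x")))
  expect_error(read_ko_annotations(short), "missing required column")
})

test_that("strain gene tables load, validate labels and round-trip", {
  header <- c("locus_tag", "ko_id", "label")
  path <- write_fixture_tsv(header, list(
    c("b0002", "K12524", "essential_experimental"),
    c("b9999", "", "nonessential"),
    c("b0005", "K00005", "unknown")))
  tab <- read_strain_genes(path, "eco")

  expect_equal(tab$strain_id, rep("eco", 3))
  expect_equal(tab$ko_id[1], "K12524")
  expect_true(is.na(tab$ko_id[2]))

  out <- tempfile(fileext = ".tsv")
  write_strain_genes(tab, out)
  expect_identical(read_strain_genes(out, "eco"), tab)

  bad_label <- write_fixture_tsv(header, list(c("b0001", "K00001", "maybe")))
  expect_error(read_strain_genes(bad_label, "eco"), "unknown essentiality label")

  dup <- write_fixture_tsv(header, list(
    c("b0001", "K00001", "nonessential"),
    c("b0001", "K00002", "nonessential")))
  expect_error(read_strain_genes(dup, "eco"), "duplicate locus_tag")
})

make_ann <- function(kos, rxns) {
  df <- data.frame(ko_id = kos,
                   kegg_pathway_annotation = "", cog_annotation = "",
                   gene_name = "", description = "",
                   stringsAsFactors = FALSE)
  df$reaction_ids <- rxns
  df[, c("ko_id", "kegg_pathway_annotation", "cog_annotation",
         "reaction_ids", "gene_name", "description")]
}

test_that("reaction expansion adds exactly the single-hop shared-#R KOs", {
  ann <- make_ann(c("K00001", "K00002", "K00003"),
                  list("R001", "R001", "R002"))
  expect_setequal(expand_by_reaction("K00001", ann), c("K00001", "K00002"))

  lonely <- make_ann(c("K00001", "K00002"), list("R001", "R002"))
  expect_setequal(expand_by_reaction("K00001", lonely), "K00001")

  # unknown KOs pass through; empty reaction sets contribute nothing
  expect_setequal(expand_by_reaction(c("K99999"), ann), "K99999")

  # single-hop, not closure: a chain K1 -R1- K2 -R2- K3 grows one hop per
  # application
  chain <- make_ann(c("K00001", "K00002", "K00003"),
                    list("R001", c("R001", "R002"), "R002"))
  once <- expand_by_reaction("K00001", chain)
  expect_setequal(once, c("K00001", "K00002"))
  expect_setequal(expand_by_reaction(once, chain),
                  c("K00001", "K00002", "K00003"))
})

test_that("expansion output is always a superset of its input", {
  set.seed(42)
  for (rep in 1:20) {
    nk <- sample(3:15, 1)
    ann <- make_ann(sprintf("K%05d", 1:nk),
                    lapply(1:nk, function(i)
                      sprintf("R%03d", sample(1:5, sample(0:3, 1)))))
    seed <- sample(ann$ko_id, sample(1:nk, 1))
    out <- expand_by_reaction(seed, ann)
    expect_true(all(seed %in% out))
    # brute-force pairwise check
    seed_rxn <- unlist(ann$reaction_ids[ann$ko_id %in% seed])
    manual <- union(seed, ann$ko_id[vapply(ann$reaction_ids, function(r)
      length(intersect(r, seed_rxn)) > 0, logical(1))])
    expect_setequal(out, manual)
  }
})

strain_tab <- function(sid, locus, ko, label) {
  data.frame(strain_id = sid, locus_tag = locus, ko_id = ko, label = label,
             stringsAsFactors = FALSE)
}

test_that("essentiality tallies classify each strain into one bucket", {
  s1 <- strain_tab("s1", c("a1", "a2"), c("K00001", "K00002"),
                   c("essential_experimental", "nonessential"))
  s2 <- strain_tab("s2", c("b1", "b2"), c("K00001", "K00002"),
                   c("essential_experimental", "nonessential"))
  s3 <- strain_tab("s3", "c1", "K00002", "nonessential")

  tal <- tally_ko_essentiality(list(s1, s2, s3))
  k1 <- tal[tal$ko_id == "K00001", ]
  expect_equal(c(k1$eg_e, k1$eg_m, k1$non_eg), c(2L, 0L, 0L))
  expect_equal(tal$n_strains, c(3L, 3L))
  # KO absent from all strains simply does not appear in the tally
  expect_false("K09999" %in% tal$ko_id)

  # remapped gene moves a non-essential KO into the missing-essential bucket
  tal2 <- tally_ko_essentiality(list(s1, s2, s3),
                                remapped = list(s3 = "c1"))
  k2 <- tal2[tal2$ko_id == "K00002", ]
  expect_equal(k2$eg_m, 1L)
  expect_equal(k2$non_eg, 2L)

  # experimental essentiality takes precedence over remapping
  tal3 <- tally_ko_essentiality(list(s1, s2), remapped = list(s1 = "a1"))
  expect_equal(tal3$eg_e[tal3$ko_id == "K00001"], 2L)
  expect_equal(tal3$eg_m[tal3$ko_id == "K00001"], 0L)
})

test_that("mixed labels within one strain follow the precedence rule", {
  # one KO on two genes: essential wins over missing, missing over non
  s <- strain_tab("s1", c("g1", "g2"), c("K00001", "K00001"),
                  c("essential_experimental", "nonessential"))
  tal <- tally_ko_essentiality(list(s))
  expect_equal(tal$eg_e, 1L)
  expect_equal(tal$non_eg, 0L)

  s2 <- strain_tab("s1", c("g1", "g2"), c("K00001", "K00001"),
                   c("nonessential", "nonessential"))
  tal2 <- tally_ko_essentiality(list(s2), remapped = list(s1 = "g2"))
  expect_equal(tal2$eg_m, 1L)
  expect_equal(tal2$non_eg, 0L)
})

test_that("tally integrity: bad remapped tags error, unknown labels warn", {
  s1 <- strain_tab("s1", "g1", "K00001", "nonessential")
  expect_error(tally_ko_essentiality(list(s1), remapped = list(s1 = "nope")),
               "not found in strain")
  expect_error(tally_ko_essentiality(list(s1), remapped = list(zz = "g1")),
               "not in the panel")
  s2 <- strain_tab("s1", c("g1", "g2"), c("K00001", "K00002"),
                   c("nonessential", "unknown"))
  expect_warning(tal <- tally_ko_essentiality(list(s2)), "unknown label")
  expect_false("K00002" %in% tal$ko_id)
})

test_that("tally buckets partition the strains carrying each KO", {
  set.seed(7)
  for (rep in 1:10) {
    nstr <- sample(2:6, 1)
    tabs <- lapply(seq_len(nstr), function(s) {
      ng <- sample(3:8, 1)
      strain_tab(sprintf("s%d", s), sprintf("s%d_g%d", s, 1:ng),
                 sprintf("K%05d", sample(1:6, ng, replace = TRUE)),
                 sample(c("essential_experimental", "nonessential"), ng,
                        replace = TRUE))
    })
    tal <- tally_ko_essentiality(tabs)
    for (ko in tal$ko_id) {
      carriers <- sum(vapply(tabs, function(t) ko %in% t$ko_id, logical(1)))
      row <- tal[tal$ko_id == ko, ]
      expect_equal(row$eg_e + row$eg_m + row$non_eg, carriers)
    }
  }
})
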