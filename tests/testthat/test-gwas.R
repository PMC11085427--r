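test_that("parse_mapped_genes splits on all separators and drops markers", {
  expect_setequal(parse_mapped_genes("APOE - APOC1"), c("APOC1", "APOE"))
  expect_setequal(parse_mapped_genes("no mapped genes x MYO6"), "MYO6")
  expect_equal(parse_mapped_genes(""), character(0))
  expect_setequal(parse_mapped_genes("A1; B1, C1"), c("A1", "B1", "C1"))
  expect_setequal(parse_mapped_genes("APOE (also APOC1)"), c("APOC1", "APOE"))
  expect_equal(parse_mapped_genes("intergenic"), character(0))
  # allele tokens and rs ids in interaction cells are not genes
  expect_setequal(parse_mapped_genes("rs3798440; A x rs9350602; C"),
                  character(0))
})

test_that("filter_associations keeps includes, drops excludes, idempotent", {
  assoc <- data.frame(
    accession = paste0("GCST", 1:4),
    trait = c("hypertension", "Pulmonary arterial hypertension",
              "preeclampsia", "systolic hypertension"),
    rsid = paste0("rs", 1:4), mapped_gene_raw = LETTERS[1:4],
    stringsAsFactors = FALSE
  )
  excl <- default_exclude_terms("hypertension")
  kept <- filter_associations(assoc, "hypertension", excl)
  expect_equal(kept$accession, c("GCST1", "GCST4"))
  expect_identical(filter_associations(kept, "hypertension", excl), kept)
  # empty exclude list keeps all include matches
  expect_equal(nrow(filter_associations(assoc, "hypertension")), 3L)
  expect_error(filter_associations(assoc, character(0)), "include_terms")
})

test_that("build_trait_gene_set pools genes with provenance", {
  assoc <- data.frame(
    accession = c("GCST1", "GCST2"),
    trait = "hypertension",
    rsid = c("rs1", "rs2"),
    mapped_gene_raw = c("A1", "A1 - B1"),
    stringsAsFactors = FALSE
  )
  ts <- build_trait_gene_set(assoc, "hypertension")
  expect_setequal(ts$genes, c("A1", "B1"))
  expect_equal(nrow(ts$provenance[["A1"]]), 2L)
  expect_equal(nrow(ts$provenance[["B1"]]), 1L)
  expect_equal(ts$n_associations, 2L)
})

test_that("all-intergenic rows give an empty gene set, not an error", {
  assoc <- data.frame(
    accession = paste0("GCST", 1:3), trait = "hypertension",
    rsid = paste0("rs", 1:3),
    mapped_gene_raw = rep("no mapped genes", 3),
    stringsAsFactors = FALSE
  )
  ts <- build_trait_gene_set(assoc, "hypertension")
  expect_length(ts$genes, 0L)
  expect_equal(ts$n_associations, 3L)
  expect_warning(build_trait_gene_set(assoc[0, ], "hypertension"), "no assoc")
})

test_that("trait sets match hand enumeration on a synthetic 10-row export", {
  raw <- c("A1", "A1 - B1", "no mapped genes", "C1; D1", "B1",
           "E1 (also F1)", "no mapped genes x G1", "H1", "A1, C1", "I1")
  assoc <- data.frame(accession = sprintf("GCST%02d", 1:10),
                      trait = "hypertension", rsid = sprintf("rs%d", 1:10),
                      mapped_gene_raw = raw, stringsAsFactors = FALSE)
  ts <- build_trait_gene_set(assoc, "hypertension")
  # brute-force: parse each row independently and union
  expected <- sort(unique(unlist(lapply(raw, parse_mapped_genes))))
  expect_equal(ts$genes, expected)
  # every gene reachable from >= 1 surviving association
  for (g in ts$genes) expect_gte(nrow(ts$provenance[[g]]), 1L)
})

test_that("union_trait_sets merges genes and provenance", {
  mk <- function(label, genes, acc) {
    assoc <- data.frame(accession = acc, trait = label,
                        rsid = paste0("rs", seq_along(genes)),
                        mapped_gene_raw = genes, stringsAsFactors = FALSE)
    build_trait_gene_set(assoc, label)
  }
  t1 <- mk("hypertension", c("A1", "B1"), "GCST1")
  t2 <- mk("atherosclerosis", c("B1", "C1"), "GCST2")
  u <- union_trait_sets(list(t1, t2))
  expect_setequal(u$genes, c("A1", "B1", "C1"))
  expect_equal(nrow(u$provenance[["B1"]]), 2L)
  expect_named(u$per_trait, c("hypertension", "atherosclerosis"))
  # disjoint sets: union size is the sum
  t3 <- mk("arterial_stiffness", c("X1", "Y1", "Z1", "W1"), "GCST3")
  expect_length(union_trait_sets(list(t1, t3))$genes, 6L)
})

test_that("union size never exceeds the sum, equality iff disjoint (property)", {
  set.seed(7)
  pool <- sprintf("G%03d", 1:60)
  for (i in 1:20) {
    gs <- lapply(1:3, function(j) sample(pool, sample(5:20, 1)))
    sets <- lapply(seq_along(gs), function(j) {
      assoc <- data.frame(accession = "GCSTX", trait = "t",
                          rsid = paste0("rs", seq_along(gs[[j]])),
                          mapped_gene_raw = gs[[j]], stringsAsFactors = FALSE)
      build_trait_gene_set(assoc, paste0("t", j))
    })
    u <- union_trait_sets(sets)
    expect_equal(sort(u$genes), sort(Reduce(union, gs)))
    expect_lte(length(u$genes), sum(lengths(gs)))
    disjoint <- sum(lengths(gs)) == length(unique(unlist(gs)))
    expect_equal(length(u$genes) == sum(lengths(gs)), disjoint)
  }
})

test_that("the bundled association rows curate into trait sets", {
  assoc <- bundled_gwas_associations()
  hyp <- build_trait_gene_set(
    filter_associations(assoc, "hypertension",
                        default_exclude_terms("hypertension")),
    "hypertension")
  expect_true(all(c("ALDH2", "CAPZA1", "MYO6", "SARM1") %in% hyp$genes))
  # SARM1 arrives via an (also VTN) cell; VTN is carried too
  expect_true("VTN" %in% hyp$genes)
  stiff <- build_trait_gene_set(
    filter_associations(assoc, "arterial stiffness"), "arterial_stiffness")
  expect_setequal(stiff$genes, c("PPARG", "TCF20"))
})
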