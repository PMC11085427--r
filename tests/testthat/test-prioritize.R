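test_that("candidate_degs cells match per-gene brute-force classification", {
  set.seed(41)
  pool <- sprintf("G%03d", 1:150)
  studies <- lapply(1:3, function(i) study_from(paste0("S", i), sample(pool, 40)))
  mk_trait <- function(label, genes) {
    assoc <- data.frame(accession = "GCSTX", trait = label,
                        rsid = paste0("rs", seq_along(genes)),
                        mapped_gene_raw = genes, stringsAsFactors = FALSE)
    build_trait_gene_set(assoc, label)
  }
  traits <- list(mk_trait("hypertension", sample(pool, 30)),
                 mk_trait("atherosclerosis", sample(pool, 15)))
  res <- candidate_degs(studies, traits)
  for (i in 1:3) {
    for (j in 1:2) {
      oracle <- sort(Filter(function(g) {
        g %in% studies[[i]]$genes && g %in% traits[[j]]$genes
      }, pool))
      expect_equal(res$cells[[i]][[j]], oracle)
      expect_equal(unname(res$cell_counts[i, j]), length(oracle))
    }
  }
  expect_equal(res$pooled, sort(unique(unlist(res$cells))))
})

test_that("candidate_degs flags genes hit by two traits in one study", {
  studies <- list(study_from("S1", c("DUAL1", "ONLY1")))
  mk <- function(label, genes) {
    assoc <- data.frame(accession = "GCSTX", trait = label,
                        rsid = paste0("rs", seq_along(genes)),
                        mapped_gene_raw = genes, stringsAsFactors = FALSE)
    build_trait_gene_set(assoc, label)
  }
  traits <- list(mk("hypertension", c("DUAL1", "ONLY1")),
                 mk("atherosclerosis", "DUAL1"))
  res <- candidate_degs(studies, traits)
  expect_equal(res$multi_trait$gene, "DUAL1")
  expect_match(res$multi_trait$traits, "hypertension;atherosclerosis")
  # a study disjoint from every trait yields empty cells
  res2 <- candidate_degs(list(study_from("S9", c("ZZ1", "ZZ2"))), traits)
  expect_true(all(lengths(res2$cells$S9) == 0))
  expect_length(res2$pooled, 0L)
})

test_that("evidence matrix flags agree with the curated inputs", {
  rec <- bundled_recurrent_candidates()
  m <- build_evidence_matrix(
    candidate_deg_pool = bundled_candidate_deg_pool(),
    candidate_ur_pool = candidate_urs(
      bundled_ur_candidates(),
      sort(unique(unlist(bundled_ur_candidates()))))$pooled,
    recurrent_ge2 = rec$ge2,
    recurrent_ge3 = rec$ge3,
    placement_union = placement_gene_union(
      placement_table(collection_universe(bundled_pathways()),
                      bundled_pathways(), min_hits = 2)),
    lit_top_sets = top_literature_sets(bundled_literature_counts())$sets
  )
  capza1 <- m[m$gene == "CAPZA1", ]
  expect_true(capza1$recurrent_ge3)
  expect_false(capza1$in_pathway_table)
  ncr3 <- m[m$gene == "NCR3", ]
  expect_true(all(unlist(ncr3[c("is_candidate_deg", "is_candidate_ur",
                                "recurrent_ge2", "in_pathway_table")])))
  expect_false("ZZZNOT1" %in% m$gene)
  # every ge3 gene is also ge2
  expect_true(all(m$recurrent_ge2[m$recurrent_ge3]))
  # every true flag has provenance
  prov <- attr(m, "provenance")
  for (g in m$gene[m$top_lit]) {
    expect_true(length(prov[[g]]$literature) >= 1L)
  }
})

test_that("build_evidence_matrix rejects inconsistent recurrence inputs", {
  expect_error(
    build_evidence_matrix("A1", character(0), character(0), "A1",
                          character(0), character(0)),
    "subset"
  )
})

test_that("the six criteria reproduce the published intersections", {
  report <- bundled_prioritization()
  crit <- report$criteria_sets
  expect_equal(crit$a, c("GNA13", "NCR3", "SARM1"))
  expect_equal(crit$b, c("LSP1", "NCR3", "TCF20"))
  expect_equal(crit$f, "CAPZA1")
  expect_equal(crit$e, c("IRF5", "LDLR", "MKNK1", "MYO6", "NCR3", "TCF7L2"))
})

test_that("the priority set is the published 20-gene list, ranked and tied alphabetically", {
  report <- bundled_prioritization()
  expect_equal(sort(report$priority_genes$gene),
               c("ALDH2", "APOE", "CAPZA1", "CYP11B2", "GNA13", "IL6",
                 "IRF5", "LDLR", "LPL", "LSP1", "MKNK1", "MMP3", "MTHFR",
                 "MYO6", "NCR3", "PPARG", "SARM1", "TCF20", "TCF7L2", "TNF"))
  df <- report$priority_genes
  expect_true(all(diff(df$n_criteria_hit) <= 0))
  for (n in unique(df$n_criteria_hit)) {
    block <- df$gene[df$n_criteria_hit == n]
    expect_equal(block, sort(block))
  }
  # priority set == union of the six criteria sets, exactly
  expect_setequal(df$gene, unique(unlist(report$criteria_sets)))
  # stricter mode keeps only multi-criteria genes
  strict <- bundled_prioritization(min_criteria = 2)
  expect_true(all(strict$priority_genes$n_criteria_hit >= 2))
  expect_true(all(strict$priority_genes$gene %in% df$gene))
})

test_that("an all-false matrix yields an empty report", {
  m <- build_evidence_matrix("A1", character(0), character(0), character(0),
                             character(0), character(0))
  rep0 <- priority_report(m)
  expect_equal(nrow(rep0$priority_genes), 0L)
  expect_true(all(lengths(rep0$criteria_sets) == 0))
})

test_that("planted genes enter the priority set and nothing bypasses the criteria", {
  params <- small_params()
  for (seed in 1:5) {
    bundle <- generate_bundle(params, seed = seed)
    planted <- bundle$truth$planted_priority_genes
    trait_sets <- lapply(names(bundle$truth$trait_genes), function(tr) {
      structure(list(trait_label = tr, genes = bundle$truth$trait_genes[[tr]],
                     provenance = list(), n_associations = 0L),
                class = "trait_gene_set")
    })
    cand <- candidate_degs(bundle$studies, trait_sets)
    placement <- placement_table(cand$pooled, bundle$collection, min_hits = 2)
    lit <- top_literature_sets(
      bundle$lit_counts,
      data.frame(pool = c("deg", "ur"), category = "cvd_snp",
                 min_count = params$lit_threshold))
    rec2 <- genes_in_at_least(bundle$studies, 2)
    rec3 <- genes_in_at_least(bundle$studies, 3)
    report <- prioritize_candidates(
      candidate_deg_pool = cand$pooled,
      candidate_ur_pool = intersect(
        unique(unlist(bundle$truth$trait_genes)), planted),
      recurrent_ge2 = intersect(cand$pooled, rec2),
      recurrent_ge3 = intersect(cand$pooled, rec3),
      placement_union = placement_gene_union(placement),
      lit_top_sets = lit$sets
    )
    expect_true(all(planted %in% report$priority_genes$gene),
                label = paste("seed", seed))
    expect_true(all(report$priority_genes$n_criteria_hit >= 1))
    expect_setequal(report$priority_genes$gene,
                    unique(unlist(report$criteria_sets)))
  }
})

test_that("print, summary, plot and as.data.frame methods work", {
  report <- bundled_prioritization()
  expect_output(print(report), "20 top-priority genes")
  expect_output(summary(report), "\\(a\\) n = 3")
  expect_s3_class(as.data.frame(report), "data.frame")
  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_silent(plot(report))
  grDevices::dev.off()
  expect_true(file.size(tmp) > 0)
})
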