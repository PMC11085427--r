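test_that("hypergeometric right tail matches brute-force enumeration (small N)", {
  for (N in c(5L, 6L, 8L, 9L)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_right_tail(N, K, n, k),
                       enum_hyper_tail(N, K, n, k),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("hypergeometric right tail matches the combinatorial closed form for all N <= 12", {
  for (N in 1:12) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_right_tail(N, K, n, k),
                       choose_hyper_tail(N, K, n, k),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("hypergeometric examples and edge cases", {
  expect_identical(hypergeom_right_tail(100, 10, 5, 0), 1)
  # drawing 4 of the 5 marked among C(10,4)=210 draws: 5 favourable
  expect_equal(hypergeom_right_tail(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_error(hypergeom_right_tail(10, 11, 5, 2), "parameters")
  expect_error(hypergeom_right_tail(10, 5, 4, 5), "parameters")
  expect_error(hypergeom_right_tail(10, 5, 4, -1), "parameters")
})

test_that("right tail is non-increasing in k at fixed N, K, n", {
  for (parms in list(c(50, 10, 20), c(200, 30, 50), c(12, 6, 6))) {
    N <- parms[1]; K <- parms[2]; n <- parms[3]
    p <- vapply(0:min(K, n), function(k) hypergeom_right_tail(N, K, n, k),
                numeric(1))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("bh_adjust matches the hand-applied step-up ramp", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(23)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), ramp_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("bh_adjust is permutation-equivariant", {
  set.seed(5)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("run_ora handles disjoint queries and restricts to the universe", {
  col <- gene_set_collection(list(
    list(set_id = "S1", name = "S1", source_tag = "KEGG",
         genes = c("A1", "B1")),
    list(set_id = "S2", name = "S2", source_tag = "KEGG",
         genes = c("C1", "D1"))
  ))
  res <- run_ora(c("X1", "Y1"), col, universe = c("A1", "B1", "C1", "D1",
                                                  "X1", "Y1"))
  expect_true(all(res$k == 0))
  expect_true(all(res$p_right == 1))
  # query genes outside the universe are dropped with a message
  expect_message(res2 <- run_ora(c("A1", "ZZZ"), col), "dropped")
  expect_equal(res2$n[1], 1L)
  expect_error(run_ora("A1", col, universe = character(0)), "empty universe")
})

test_that("run_ora agrees with the enumeration oracle on exact draws", {
  # universe of 10, pathway of 5, query of 4 genes fully inside the pathway
  col <- gene_set_collection(list(
    list(set_id = "S1", name = "S1", source_tag = "KEGG",
         genes = sprintf("G%02d", 1:5))
  ))
  res <- run_ora(sprintf("G%02d", 1:4), col,
                 universe = sprintf("G%02d", 1:10))
  expect_equal(res$p_right, enum_hyper_tail(10, 5, 4, 4), tolerance = 1e-12)
  # query = universe forces k = K and p = 1
  res_full <- run_ora(sprintf("G%02d", 1:10), col,
                      universe = sprintf("G%02d", 1:10))
  expect_equal(res_full$k, res_full$K)
  expect_equal(res_full$p_right, 1)
})

test_that("a planted enriched pathway gets the smallest ORA p-value", {
  params <- small_params()
  recovered <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    bundle <- generate_bundle(params, seed = seed)
    deg_union <- unique(unlist(lapply(bundle$studies, `[[`, "genes")))
    res <- run_ora(deg_union, bundle$collection,
                   universe = collection_universe(bundle$collection))
    if (res$set_id[1] %in% bundle$truth$planted_pathways) {
      recovered <- recovered + 1L
    }
  }
  expect_gte(recovered, n_seeds - 1L)
})

test_that("placement_table reproduces the curated placement evidence", {
  col <- bundled_pathways()
  tab <- placement_table(collection_universe(col), col, min_hits = 2)
  vegfa <- tab[tab$set_id == "VEGFA-VEGFR2 Signaling Pathway", ]
  expect_equal(vegfa$hit_count, 6L)
  expect_equal(strsplit(vegfa$hits, ";")[[1]],
               c("CSK", "MKNK1", "MYO6", "PTPRJ", "SMARCA2", "TNXB"))
  expect_length(placement_gene_union(tab), 33L)
  # rows sorted by hit count descending then set_id
  expect_true(all(diff(tab$hit_count) <= 0))
})

test_that("placement_table filters by min_hits and the union stays in the query", {
  col <- bundled_pathways()
  q <- c("LDLR", "LPL", "NOTAGENE1")
  tab <- placement_table(q, col, min_hits = 2)
  expect_true(all(placement_gene_union(tab) %in% q))
  expect_true(all(tab$hit_count >= 2))
  none <- placement_table("NOTAGENE1", col, min_hits = 1)
  expect_equal(nrow(none), 0L)
  expect_length(placement_gene_union(none), 0L)
})
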