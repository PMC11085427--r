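test_that("two-target regulator case matches direct enumeration", {
  # regulator whose only 2 targets are both DEGs; universe 100, 10 DEGs:
  # P = C(10,2)/C(100,2) = 45/4950
  universe <- sprintf("G%03d", 1:100)
  degs <- study_from("S1", universe[1:10])
  net <- regulator_network(rep("REG1", 2), universe[1:2], alias_map = NULL)
  res <- ur_overlap_scan(degs, net, universe)
  expect_equal(res$p_right, 45 / 4950, tolerance = 1e-12)
  expect_equal(res$overlap_k, 2L)
  expect_false(res$is_also_deg)
})

test_that("zero-overlap regulators get p = 1 and DEG regulators are flagged", {
  universe <- sprintf("G%03d", 1:50)
  degs <- study_from("S1", universe[1:5])
  net <- regulator_network(c("REG1", "REG1", "G001", "G001"),
                           c(universe[40], universe[41],
                             universe[42], universe[3]), alias_map = NULL)
  res <- ur_overlap_scan(degs, net, universe)
  expect_equal(res$p_right[res$regulator == "REG1"], 1)
  expect_true(res$is_also_deg[res$regulator == "G001"])
  expect_error(ur_overlap_scan(degs, net, character(0)), "empty universe")
})

test_that("scan p-values equal the enrichment statistic on identical parameters", {
  set.seed(31)
  universe <- sprintf("G%03d", 1:80)
  degs <- study_from("S1", sample(universe, 20))
  regs <- paste0("REG", 1:6)
  edges_r <- character(0); edges_t <- character(0)
  for (r in regs) {
    tgt <- sample(universe, sample(5:15, 1))
    edges_r <- c(edges_r, rep(r, length(tgt)))
    edges_t <- c(edges_t, tgt)
  }
  net <- regulator_network(edges_r, edges_t, alias_map = NULL)
  res <- ur_overlap_scan(degs, net, universe)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_right[i],
                 hypergeom_right_tail(80, res$n_targets_in_universe[i],
                                      20, res$overlap_k[i]),
                 tolerance = 1e-14)
  }
  expect_equal(res$q_bh, bh_adjust(res$p_right))
})

test_that("planted regulators with biased targets rank first", {
  params <- small_params()
  top_hits <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    bundle <- generate_bundle(params, seed = seed)
    deg_union <- unique(unlist(lapply(bundle$studies, `[[`, "genes")))
    pooled <- study_from("POOL", deg_union)
    res <- ur_overlap_scan(pooled, bundle$network,
                           synthetic_universe(params))
    if (res$regulator[1] %in% bundle$truth$planted_regulators) {
      top_hits <- top_hits + 1L
    }
  }
  expect_gte(top_hits, n_seeds - 1L)
})

test_that("candidate_urs intersects per study and pools the union", {
  ur_lists <- list(P1 = c("APOE", "EBF1", "XXX1"),
                   P2 = c("TNF", "YYY1"),
                   P3 = character(0))
  gwas <- c("APOE", "EBF1", "TNF", "LDLR")
  res <- candidate_urs(ur_lists, gwas)
  expect_equal(res$per_study$P1, c("APOE", "EBF1"))
  expect_equal(res$per_study$P2, "TNF")
  expect_equal(res$per_study$P3, character(0))
  expect_equal(res$pooled, c("APOE", "EBF1", "TNF"))
  expect_setequal(res$pooled, unique(unlist(res$per_study)))
  expect_error(candidate_urs(list(c("A1")), gwas), "named")
})

test_that("the bundled per-study UR lists pool to 42 distinct genes", {
  ur_lists <- bundled_ur_candidates()
  res <- candidate_urs(ur_lists, sort(unique(unlist(ur_lists))))
  expect_equal(vapply(res$per_study, length, integer(1)),
               c(P1 = 3L, P2 = 6L, P3 = 7L, P4 = 25L, P5 = 22L))
  expect_equal(res$per_study$P1, c("APOE", "EBF1", "ZBTB10"))
  expect_length(res$pooled, 42L)
})

test_that("null scans are calibrated against the exact attained level", {
  # With uniform DEG draws and uniform targets, the rejection fraction at
  # alpha = 0.05 must match the exact null rejection probability of the
  # discrete test, E[P(p <= alpha)] over the regulator target sizes, which
  # for a discrete tail is at most alpha.
  set.seed(2024)
  N <- 400L; n_deg <- 80L; n_reg <- 40L; n_scans <- 200L
  universe <- sprintf("G%04d", seq_len(N))
  k_sizes <- sample(10:60, n_reg, replace = TRUE)
  # exact attained level per regulator from the choose-based oracle
  attained <- vapply(k_sizes, function(K) {
    tails <- vapply(0:min(K, n_deg),
                    function(k) choose_hyper_tail(N, K, n_deg, k), numeric(1))
    k_star <- which(tails <= 0.05)[1] - 1L
    if (is.na(k_star)) 0 else tails[k_star + 1L]
  }, numeric(1))
  expected <- mean(attained)
  fractions <- numeric(n_scans)
  for (s in seq_len(n_scans)) {
    degs <- study_from("S1", sample(universe, n_deg))
    edges_r <- rep(paste0("REG", seq_len(n_reg)), k_sizes)
    edges_t <- unlist(lapply(k_sizes, function(K) sample(universe, K)))
    net <- regulator_network(edges_r, edges_t, alias_map = NULL)
    res <- ur_overlap_scan(degs, net, universe)
    fractions[s] <- mean(res$p_right <= 0.05)
  }
  se <- stats::sd(fractions) / sqrt(n_scans)
  expect_lt(abs(mean(fractions) - expected), 3 * se)
  # validity against the nominal level: never above 5% beyond noise
  expect_lte(mean(fractions), 0.05 + 3 * se)
})
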