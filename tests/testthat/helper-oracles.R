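# Independent oracles used across the suite.

# Hypergeometric right tail by brute-force enumeration of all C(N, n) draws:
# mark genes 1..K, count draws containing >= k marked.
enum_hyper_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(if (k > 0) 0 else 1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  sum(hits >= k) / ncol(draws)
}

# Hypergeometric right tail from the combinatorial closed form (choose-based,
# no stats:: tail routine involved).
choose_hyper_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  xs <- k:min(K, n)
  xs <- xs[n - xs <= N - K]
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Hand-applied BH step-up: p(i) * m / i with cumulative minimum from the top.
ramp_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Small, fast synthetic parameter set used throughout the tests; the same
# generative structure as the defaults at reduced size.
small_params <- function(...) {
  # sizes scaled down from the default study conditions while preserving the
  # DEG-union-to-universe ratio (~0.3), which is what the planted-signal
  # factors act against
  defaults <- list(
    universe_size = 4000L,
    study_sizes = c(300L, 250L, 200L, 350L, 300L),
    shared_core_size = 30L,
    trait_sizes = c(hypertension = 80L, atherosclerosis = 40L,
                    arterial_stiffness = 30L),
    trait_deg_overlap = 0.3,
    n_planted_priority = 5L,
    n_pathways = 20L, pathway_size = 25L,
    n_planted_pathways = 3L, pathway_enrichment = 5,
    n_regulators = 30L, targets_per_regulator = 30L,
    n_planted_regulators = 3L, regulator_bias = 5,
    lit_threshold = 30L
  )
  over <- list(...)
  defaults[names(over)] <- over
  do.call(synthetic_params, defaults)
}

study_from <- function(id, genes) study_gene_set(id, genes, alias_map = NULL)
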