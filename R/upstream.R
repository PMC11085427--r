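# Upstream-regulator overlap enrichment and UR x GWAS intersection.

#' Overlap-enrichment scan for upstream regulators
#'
#' For each regulator in the network with at least one target in the
#' universe, tests whether its targets overlap the study's DEGs more than
#' expected by chance: p = P(X >= overlap) for X hypergeometric(|universe|,
#' targets-in-universe, |DEGs|). BH adjustment is applied across regulators.
#' This open overlap statistic stands behind the module surface in place of
#' proprietary knowledge-base scoring; precomputed regulator lists can bypass
#' it entirely via [candidate_urs()].
#'
#' Regulator tokens that do not look like gene symbols (spaces, lowercase
#' chemical names, etc.) are dropped at ingestion, since only gene-symbol
#' regulators can be intersected with GWAS genes downstream.
#'
#' @param degs a [study_gene_set()].
#' @param network a [regulator_network()].
#' @param universe background gene vector (non-empty); DEGs are restricted to
#'   it.
#' @param alpha significance level used only for the \code{significant}
#'   convenience column (default q <= 0.01).
#' @return data frame of class \code{ur_result}: \code{regulator},
#'   \code{n_targets_in_universe}, \code{overlap_k}, \code{p_right},
#'   \code{q_bh}, \code{is_also_deg}, \code{significant}; sorted by
#'   \code{p_right} ascending, ties by regulator.
#' @export
ur_overlap_scan <- function(degs, network, universe, alpha = 0.01) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (length(network$targets_by_regulator) == 0L) {
    stop("empty regulator network", call. = FALSE)
  }
  universe <- sort(unique(universe))
  deg_genes <- intersect(degs$genes, universe)
  N <- length(universe)
  n <- length(deg_genes)
  regs <- names(network$targets_by_regulator)
  regs <- regs[grepl("^[A-Z0-9][A-Z0-9_.-]*$", regs)]
  rows <- lapply(regs, function(r) {
    targets <- intersect(unique(network$targets_by_regulator[[r]]), universe)
    K <- length(targets)
    if (K == 0L) return(NULL)
    k <- length(intersect(targets, deg_genes))
    data.frame(regulator = r, n_targets_in_universe = K, overlap_k = k,
               p_right = hypergeom_right_tail(N, K, n, k),
               is_also_deg = r %in% degs$genes,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no regulator has targets in the universe", call. = FALSE)
  }
  res <- do.call(rbind, rows)
  res$q_bh <- bh_adjust(res$p_right)
  res$significant <- res$q_bh <= alpha
  res <- res[order(res$p_right, res$regulator),
             c("regulator", "n_targets_in_universe", "overlap_k",
               "p_right", "q_bh", "is_also_deg", "significant")]
  rownames(res) <- NULL
  class(res) <- c("ur_result", "data.frame")
  res
}

#' Candidate upstream regulators: URs intersected with GWAS genes
#'
#' Intersects each study's upstream-regulator gene list with the pooled GWAS
#' vascular-dysfunction gene set, then pools the per-study intersections. The
#' pooled set always equals the union of the per-study sets (asserted).
#'
#' @param ur_gene_lists named list (study_id -> character vector of UR gene
#'   symbols); precomputed lists are accepted directly, or take
#'   \code{regulator} columns from [ur_overlap_scan()] output.
#' @param gwas_genes a trait gene set from [union_trait_sets()] /
#'   [build_trait_gene_set()], or a plain character vector of genes.
#' @return list with \code{per_study} (named list of sorted intersections)
#'   and \code{pooled} (sorted deduplicated union).
#' @export
candidate_urs <- function(ur_gene_lists, gwas_genes) {
  stopifnot(is.list(ur_gene_lists), length(ur_gene_lists) >= 1L)
  if (is.null(names(ur_gene_lists)) || any(!nzchar(names(ur_gene_lists)))) {
    stop("ur_gene_lists must be named by study", call. = FALSE)
  }
  gw <- if (inherits(gwas_genes, "trait_gene_set")) gwas_genes$genes else gwas_genes
  per_study <- lapply(ur_gene_lists,
                      function(g) sort(intersect(unique(g), gw)))
  pooled <- sort(unique(unlist(per_study, use.names = FALSE)))
  stopifnot(setequal(pooled, Reduce(union, per_study, character(0))))
  list(per_study = per_study, pooled = pooled)
}
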