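# Over-representation analysis (hypergeometric + BH) and pathway placement.

#' Hypergeometric right-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of seeing at
#' least k marked genes when n genes are drawn without replacement from a
#' universe of N genes of which K are marked. Evaluated via the stable
#' log-space tail routine of \code{stats::phyper}; k = 0 returns exactly 1.
#'
#' @param N universe size.
#' @param K marked genes in the universe (pathway size).
#' @param n query size.
#' @param k observed overlap, 0 <= k <= min(K, n).
#' @return right-tail probability in (0, 1].
#' @export
hypergeom_right_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L, length(k) == 1L)
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n) ||
      any(c(N, K, n, k) != round(c(N, K, n, k)))) {
    stop("hypergeometric parameters violate 0 <= K,n <= N and 0 <= k <= min(K,n)",
         call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment. Output order matches
#' input order; adjusted values are clipped at 1 and are monotone
#' non-decreasing when sorted by raw p.
#'
#' @param pvalues numeric vector with all values in (0, 1].
#' @return numeric vector of adjusted values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a query set against a collection
#'
#' One hypergeometric right-tail test per pathway set, with BH adjustment
#' across all sets in the collection. Query genes outside the universe are
#' dropped (a message reports how many); pathway genes are likewise restricted
#' to the universe.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param universe background gene vector; defaults to the union of all
#'   member genes in the collection (overridable with a background file read
#'   via [read_gene_list()]).
#' @return data frame of class \code{enrichment_result} with one row per set:
#'   \code{set_id}, \code{source_tag}, \code{N}, \code{K}, \code{n}, \code{k},
#'   \code{p_right}, \code{q_bh}, \code{hits} (semicolon-joined, sorted);
#'   ordered by \code{p_right} ascending, ties by \code{set_id}.
#' @export
run_ora <- function(query, collection, universe = NULL) {
  if (is.null(universe)) universe <- collection_universe(collection)
  universe <- sort(unique(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  dropped <- sum(!query %in% universe)
  if (dropped > 0L) {
    message(dropped, " query gene(s) outside the universe were dropped")
  }
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(collection$sets, function(s) {
    in_univ <- intersect(s$genes, universe)
    hits <- sort(intersect(in_univ, query))
    K <- length(in_univ)
    k <- length(hits)
    data.frame(set_id = s$set_id, source_tag = s$source_tag,
               N = N, K = K, n = n, k = k,
               p_right = hypergeom_right_tail(N, K, n, k),
               hits = paste(hits, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_bh <- bh_adjust(res$p_right)
  res <- res[order(res$p_right, res$set_id),
             c("set_id", "source_tag", "N", "K", "n", "k",
               "p_right", "q_bh", "hits")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Pathway placement table for candidate genes
#'
#' Lists, for every pathway set in the collection, which query genes it
#' contains, keeping rows with at least \code{min_hits} hits. This is the
#' descriptive companion to [run_ora()]: it answers "where do the candidate
#' genes sit", not "which pathways are significantly enriched". The default
#' \code{min_hits = 2} keeps pathways anchored by more than a lone gene.
#'
#' @param query character vector of candidate gene symbols.
#' @param collection a [gene_set_collection()].
#' @param min_hits minimum overlap to retain a row (>= 1).
#' @return data frame with columns \code{set_id}, \code{source_tag},
#'   \code{category}, \code{hit_count}, \code{hits} (semicolon-joined,
#'   alphabetical), sorted by \code{hit_count} descending then \code{set_id};
#'   attribute \code{gene_union} carries the deduplicated gene union across
#'   retained rows.
#' @export
placement_table <- function(query, collection, min_hits = 2L) {
  stopifnot(is.numeric(min_hits), length(min_hits) == 1L, min_hits >= 1L)
  query <- sort(unique(query))
  rows <- lapply(collection$sets, function(s) {
    hits <- sort(intersect(s$genes, query))
    data.frame(set_id = s$set_id, source_tag = s$source_tag,
               category = if (is.null(s$category)) NA_character_ else s$category,
               hit_count = length(hits),
               hits = paste(hits, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$hit_count >= min_hits, , drop = FALSE]
  tab <- tab[order(-tab$hit_count, tab$set_id), , drop = FALSE]
  rownames(tab) <- NULL
  gene_union <- sort(unique(unlist(strsplit(tab$hits, ";", fixed = TRUE),
                                   use.names = FALSE)))
  gene_union <- gene_union[nzchar(gene_union)]
  attr(tab, "gene_union") <- gene_union
  tab
}

#' Gene union of a placement table
#'
#' @param placement result of [placement_table()].
#' @return sorted character vector of distinct genes across retained rows.
#' @export
placement_gene_union <- function(placement) {
  attr(placement, "gene_union")
}
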