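# Literature-count evidence sets and per-gene variant ranking.

#' Top genes by literature evidence
#'
#' Selects genes from a literature-count table for one category, by exactly
#' one of two rules: a minimum publication count (\code{min_count}) or the k
#' largest counts (\code{top_k}, ties broken by count descending then symbol
#' ascending). Counts are query-date-dependent, so they arrive as a table
#' rather than being fetched live; the thresholds used with the bundled table
#' are exposed via [default_literature_thresholds()].
#'
#' @param counts a [literature_counts()] table.
#' @param category category to select within (e.g. \code{"cvd_snp"},
#'   \code{"nutrition_snp"}).
#' @param min_count minimum count rule (exclusive with \code{top_k}).
#' @param top_k top-k rule (exclusive with \code{min_count}).
#' @param pool optional pool restriction (e.g. \code{"deg"} or \code{"ur"})
#'   when the table carries a \code{pool} column.
#' @return sorted character vector of selected genes.
#' @export
top_genes <- function(counts, category, min_count = NULL, top_k = NULL,
                      pool = NULL) {
  if (is.null(min_count) == is.null(top_k)) {
    stop("specify exactly one of min_count or top_k", call. = FALSE)
  }
  df <- as.data.frame(counts)
  if (!is.null(pool)) {
    if (!"pool" %in% names(df)) stop("counts table has no pool column", call. = FALSE)
    df <- df[df$pool == pool, , drop = FALSE]
  }
  df <- df[df$category == category, , drop = FALSE]
  if (nrow(df) == 0L) return(character(0))
  # a gene may appear once per category; collapse defensively by max count
  agg <- stats::aggregate(count ~ gene, data = df, FUN = max)
  if (!is.null(min_count)) {
    return(sort(agg$gene[agg$count >= min_count]))
  }
  ord <- order(-agg$count, agg$gene)
  sort(agg$gene[ord][seq_len(min(top_k, nrow(agg)))])
}

#' Literature thresholds used with the bundled count table
#'
#' Minimum publication counts that operationalize "genes with the largest
#' literature support" for each (pool, category) combination of the bundled
#' table. The cutoffs separate the listed top genes from the unlisted
#' remainder of each search and are fully configurable.
#'
#' @return data frame with columns \code{pool}, \code{category},
#'   \code{min_count}.
#' @export
default_literature_thresholds <- function() {
  data.frame(
    pool = c("deg", "deg", "ur", "ur"),
    category = c("cvd_snp", "nutrition_snp", "cvd_snp", "nutrition_snp"),
    min_count = c(34, 5, 24, 5),
    stringsAsFactors = FALSE
  )
}

#' Top-literature gene sets under the default thresholds
#'
#' Applies [top_genes()] with [default_literature_thresholds()] to a count
#' table, returning one gene set per (pool, category) plus their union.
#'
#' @param counts a [literature_counts()] table with a \code{pool} column.
#' @param thresholds threshold table as in [default_literature_thresholds()].
#' @return list with \code{sets} (named list, names like \code{deg.cvd_snp})
#'   and \code{union} (sorted character vector).
#' @export
top_literature_sets <- function(counts,
                                thresholds = default_literature_thresholds()) {
  sets <- list()
  for (i in seq_len(nrow(thresholds))) {
    nm <- paste(thresholds$pool[i], thresholds$category[i], sep = ".")
    sets[[nm]] <- top_genes(counts, thresholds$category[i],
                            min_count = thresholds$min_count[i],
                            pool = thresholds$pool[i])
  }
  list(sets = sets, union = sort(unique(unlist(sets, use.names = FALSE))))
}

#' Rank a gene's variants by population frequency
#'
#' Returns the gene's variant records sorted by frequency descending, ties
#' broken by rsid ascending (plain string order, so the ranking is stable
#' across runs and input shufflings), truncated to the top \code{k}.
#' Records with missing frequency are appended, flagged, only when fewer than
#' \code{k} ranked records exist.
#'
#' @param variants data frame from [read_variant_table()].
#' @param gene gene symbol.
#' @param k number of variants to return (>= 1); default 10.
#' @return data frame of the gene's records with a logical
#'   \code{frequency_missing} column; zero rows (with a warning) for a gene
#'   absent from the table.
#' @export
rank_variants <- function(variants, gene, k = 10L) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1L)
  gene <- normalize_symbol(gene)
  rows <- variants[variants$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0L) {
    warning("no variant records for gene ", gene, call. = FALSE)
    rows$frequency_missing <- logical(0)
    return(rows)
  }
  rows$frequency_missing <- is.na(rows$frequency)
  ranked <- rows[!rows$frequency_missing, , drop = FALSE]
  ranked <- ranked[order(-ranked$frequency, ranked$rsid), , drop = FALSE]
  out <- utils::head(ranked, k)
  if (nrow(out) < k) {
    extra <- rows[rows$frequency_missing, , drop = FALSE]
    extra <- extra[order(extra$rsid), , drop = FALSE]
    out <- rbind(out, utils::head(extra, k - nrow(out)))
  }
  rownames(out) <- NULL
  out
}
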