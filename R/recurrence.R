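# Multi-set Venn partitioning and cross-study recurrence.

#' Venn partition of study gene sets
#'
#' Assigns every gene in the union of k study gene sets to exactly one
#' membership region, keyed by a bit pattern over the studies in input order
#' ("101" = member of studies 1 and 3 only). The all-zero pattern never
#' occurs. Region sizes always sum to the union size (asserted on every
#' call).
#'
#' @param studies list of [study_gene_set()] objects, 2 <= k <= 8 (a warning
#'   is issued above 6, where region counts become unwieldy to read).
#' @return object of class \code{venn_partition}: \code{signatures} (named
#'   list of sorted gene vectors), \code{k}, \code{study_ids}.
#' @export
venn_partition <- function(studies) {
  k <- length(studies)
  if (k < 2L || k > 8L) stop("venn_partition needs 2..8 studies", call. = FALSE)
  ids <- vapply(studies, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) stop("duplicate study_id", call. = FALSE)
  if (k > 6L) warning("more than 6 sets: region report will be large", call. = FALSE)
  gene_lists <- lapply(studies, `[[`, "genes")
  all_genes <- sort(unique(unlist(gene_lists, use.names = FALSE)))
  member <- vapply(gene_lists, function(g) all_genes %in% g,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(row) paste(as.integer(row), collapse = ""))
  signatures <- split(all_genes, sig)
  signatures <- lapply(signatures, sort)
  stopifnot(sum(lengths(signatures)) == length(all_genes))
  structure(list(signatures = signatures, k = k, study_ids = ids),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition over", x$k, "studies (",
      paste(x$study_ids, collapse = ", "), "):",
      sum(lengths(x$signatures)), "genes in",
      length(x$signatures), "regions\n")
  invisible(x)
}

#' Human-readable region labels for a Venn partition
#'
#' @param partition a [venn_partition()].
#' @return named character vector: signature -> label like \code{"P1&P4"}.
#' @export
venn_region_labels <- function(partition) {
  sigs <- names(partition$signatures)
  labs <- vapply(sigs, function(s) {
    on <- strsplit(s, "")[[1L]] == "1"
    paste(partition$study_ids[on], collapse = "&")
  }, character(1))
  stats::setNames(labs, sigs)
}

#' Region report table for a Venn partition
#'
#' @param partition a [venn_partition()].
#' @return data frame with columns \code{signature}, \code{label},
#'   \code{region_size}, \code{genes} (semicolon-joined, alphabetical),
#'   ordered by descending membership count then signature.
#' @export
venn_region_table <- function(partition) {
  sigs <- names(partition$signatures)
  n_members <- vapply(strsplit(sigs, ""),
                      function(b) sum(b == "1"), integer(1))
  df <- data.frame(
    signature = sigs,
    label = unname(venn_region_labels(partition)),
    region_size = lengths(partition$signatures),
    genes = vapply(partition$signatures, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  df <- df[order(-n_members, df$signature), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Genes present in at least m studies
#'
#' @param studies list of [study_gene_set()] objects.
#' @param m minimum number of studies, 1 <= m <= k. \code{m = 1} returns the
#'   union.
#' @return sorted character vector of genes whose membership count >= m.
#' @export
genes_in_at_least <- function(studies, m) {
  k <- length(studies)
  if (!is.numeric(m) || length(m) != 1L || m < 1L || m > k) {
    stop("m must lie in 1..", k, call. = FALSE)
  }
  tab <- table(unlist(lapply(studies, `[[`, "genes"), use.names = FALSE))
  sort(names(tab)[tab >= m])
}

#' Export study gene lists in a plain list-exchange layout
#'
#' Writes one named block per study (\code{>study_id} header line followed by
#' one gene per line), the layout accepted by list-based Venn tools. An empty
#' study writes a named empty block. [read_setlists()] round-trips the file.
#'
#' @param studies list of [study_gene_set()] objects.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
export_setlists <- function(studies, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in studies) {
    writeLines(paste0(">", s$study_id), con)
    if (length(s$genes) > 0L) writeLines(s$genes, con)
  }
  invisible(path)
}

#' Read a list-exchange file back into study gene sets
#'
#' @param path file written by [export_setlists()].
#' @param alias_map alias map for normalization.
#' @return list of [study_gene_set()] objects.
#' @export
read_setlists <- function(path, alias_map = default_alias_map()) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no named blocks in ", path, call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    id <- sub("^>", "", lines[starts[i]])
    genes <- if (ends[i] > starts[i]) {
      lines[(starts[i] + 1L):ends[i]]
    } else character(0)
    genes <- trimws(genes)
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      structure(list(study_id = id, description = "", genes = character(0),
                     direction = NULL, n_degs = 0L),
                class = "study_gene_set")
    } else {
      study_gene_set(id, genes, alias_map = alias_map)
    }
  })
}
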