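# Evidence matrix assembly, six-criteria evaluation, priority ranking.

#' Candidate DEGs: study DEG sets intersected with GWAS trait sets
#'
#' Computes, for every study x trait cell, the DEGs whose variants previous
#' GWAS have associated with that vascular-dysfunction trait, plus the pooled
#' deduplicated union over all cells ("candidate DEGs"). Genes hit by two or
#' more traits within a study are recorded separately: such double-trait
#' genes are biologically notable (the CDKN2B-AS1 / HLA-DRB1 pattern).
#'
#' @param studies list of [study_gene_set()] objects.
#' @param trait_sets list of \code{trait_gene_set} objects (one per trait).
#' @return list with \code{cells} (nested list study -> trait -> sorted gene
#'   vector), \code{cell_counts} (matrix study x trait), \code{pooled}
#'   (sorted union), \code{multi_trait} (data frame gene/study/traits).
#' @export
candidate_degs <- function(studies, trait_sets) {
  study_ids <- vapply(studies, `[[`, character(1), "study_id")
  trait_ids <- vapply(trait_sets, `[[`, character(1), "trait_label")
  cells <- stats::setNames(vector("list", length(studies)), study_ids)
  counts <- matrix(0L, length(studies), length(trait_sets),
                   dimnames = list(study_ids, trait_ids))
  multi <- list()
  for (i in seq_along(studies)) {
    per_trait <- stats::setNames(vector("list", length(trait_sets)), trait_ids)
    for (j in seq_along(trait_sets)) {
      per_trait[[j]] <- sort(intersect(studies[[i]]$genes,
                                       trait_sets[[j]]$genes))
      counts[i, j] <- length(per_trait[[j]])
    }
    cells[[i]] <- per_trait
    hits <- table(unlist(per_trait, use.names = FALSE))
    for (g in names(hits)[hits >= 2L]) {
      traits_g <- trait_ids[vapply(per_trait, function(v) g %in% v, logical(1))]
      multi[[length(multi) + 1L]] <- data.frame(
        gene = g, study_id = study_ids[i],
        traits = paste(traits_g, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  pooled <- sort(unique(unlist(cells, use.names = FALSE)))
  multi_trait <- if (length(multi) > 0L) do.call(rbind, multi) else
    data.frame(gene = character(0), study_id = character(0),
               traits = character(0), stringsAsFactors = FALSE)
  list(cells = cells, cell_counts = counts, pooled = pooled,
       multi_trait = multi_trait)
}

#' Build the per-gene evidence matrix
#'
#' Assembles the boolean evidence flags feeding the six prioritization
#' criteria, over the union of all input pools. Every true flag carries at
#' least one provenance entry describing which input supports it.
#'
#' Flags per gene:
#' \describe{
#'   \item{is_candidate_deg}{in the candidate-DEG pool (DEG x GWAS).}
#'   \item{is_candidate_ur}{in the candidate-UR pool (UR x GWAS).}
#'   \item{recurrent_ge2}{candidate DEG shared by >= 2 studies.}
#'   \item{recurrent_ge3}{candidate DEG shared by >= 3 studies (implies
#'     \code{recurrent_ge2}; enforced).}
#'   \item{in_pathway_table}{member of the retained pathway-placement union.}
#'   \item{top_lit}{in any top-literature evidence set.}
#' }
#'
#' @param candidate_deg_pool character vector (candidate DEGs).
#' @param candidate_ur_pool character vector (candidate URs).
#' @param recurrent_ge2 character vector: candidate DEGs found in >= 2
#'   studies.
#' @param recurrent_ge3 character vector: candidate DEGs found in >= 3
#'   studies.
#' @param placement_union character vector: gene union of the pathway
#'   placement table.
#' @param lit_top_sets named list of top-literature gene sets (names used as
#'   provenance categories), or a plain character vector.
#' @return object of class \code{evidence_matrix}: data frame (one row per
#'   gene, alphabetical) with the six logical flags; attribute
#'   \code{provenance} holds a per-gene list of supporting inputs.
#' @export
build_evidence_matrix <- function(candidate_deg_pool, candidate_ur_pool,
                                  recurrent_ge2, recurrent_ge3,
                                  placement_union, lit_top_sets) {
  if (!is.list(lit_top_sets)) lit_top_sets <- list(top_lit = lit_top_sets)
  if (is.null(names(lit_top_sets))) {
    names(lit_top_sets) <- paste0("lit", seq_along(lit_top_sets))
  }
  lit_union <- sort(unique(unlist(lit_top_sets, use.names = FALSE)))
  if (length(setdiff(recurrent_ge3, recurrent_ge2)) > 0L) {
    stop("recurrent_ge3 must be a subset of recurrent_ge2", call. = FALSE)
  }
  genes <- sort(unique(c(candidate_deg_pool, candidate_ur_pool,
                         recurrent_ge2, recurrent_ge3,
                         placement_union, lit_union)))
  m <- data.frame(
    gene = genes,
    is_candidate_deg = genes %in% candidate_deg_pool,
    is_candidate_ur = genes %in% candidate_ur_pool,
    recurrent_ge2 = genes %in% recurrent_ge2,
    recurrent_ge3 = genes %in% recurrent_ge3,
    in_pathway_table = genes %in% placement_union,
    top_lit = genes %in% lit_union,
    stringsAsFactors = FALSE
  )
  rownames(m) <- NULL
  prov <- lapply(genes, function(g) {
    p <- list()
    if (g %in% candidate_deg_pool) p$candidate_deg <- TRUE
    if (g %in% candidate_ur_pool) p$candidate_ur <- TRUE
    if (g %in% recurrent_ge2) p$recurrent_ge2 <- TRUE
    if (g %in% recurrent_ge3) p$recurrent_ge3 <- TRUE
    if (g %in% placement_union) p$pathway <- TRUE
    lit_hits <- names(lit_top_sets)[vapply(lit_top_sets,
                                           function(s) g %in% s, logical(1))]
    if (length(lit_hits) > 0L) p$literature <- lit_hits
    p
  })
  attr(m, "provenance") <- stats::setNames(prov, genes)
  class(m) <- c("evidence_matrix", "data.frame")
  m
}

#' The six intersection criteria
#'
#' Evaluates the six evidence intersections over an evidence matrix:
#' \describe{
#'   \item{a}{candidate DEG in >= 2 studies AND placed in a canonical pathway.}
#'   \item{b}{candidate DEG in >= 2 studies AND also a candidate UR.}
#'   \item{c}{candidate DEG AND top literature evidence.}
#'   \item{d}{candidate UR AND top literature evidence.}
#'   \item{e}{placed in a canonical pathway AND candidate UR.}
#'   \item{f}{candidate DEG in >= 3 studies.}
#' }
#'
#' @param matrix an [build_evidence_matrix()] result.
#' @return named list \code{a}..\code{f} of sorted gene vectors.
#' @export
criteria_intersections <- function(matrix) {
  stopifnot(inherits(matrix, "evidence_matrix"), nrow(matrix) > 0L)
  m <- matrix
  pick <- function(cond) sort(m$gene[cond])
  list(
    a = pick(m$recurrent_ge2 & m$is_candidate_deg & m$in_pathway_table),
    b = pick(m$recurrent_ge2 & m$is_candidate_deg & m$is_candidate_ur),
    c = pick(m$is_candidate_deg & m$top_lit),
    d = pick(m$is_candidate_ur & m$top_lit),
    e = pick(m$in_pathway_table & m$is_candidate_ur),
    f = pick(m$is_candidate_deg & m$recurrent_ge3)
  )
}

#' Priority report: ranked top-priority candidate genes
#'
#' Evaluates the six criteria and ranks their union by the number of criteria
#' each gene satisfies (descending), ties broken alphabetically. The priority
#' set is exactly the union of the six criteria sets (asserted); an optional
#' stricter mode keeps only genes satisfying at least \code{min_criteria}.
#'
#' @param matrix an [build_evidence_matrix()] result.
#' @param min_criteria minimum number of satisfied criteria to retain a gene
#'   (default 1 = plain union).
#' @param manifest optional list of run metadata stored on the report.
#' @return object of class \code{priority_report}: \code{criteria_sets},
#'   \code{priority_genes} (data frame gene / n_criteria_hit / per-criterion
#'   flags), \code{matrix}, \code{manifest}.
#' @export
priority_report <- function(matrix, min_criteria = 1L, manifest = list()) {
  crit <- criteria_intersections(matrix)
  all_genes <- sort(unique(unlist(crit, use.names = FALSE)))
  flags <- vapply(crit, function(s) all_genes %in% s,
                  logical(length(all_genes)))
  if (length(all_genes) == 1L) flags <- rbind(flags)  # keep 1 x 6 shape
  n_hit <- if (length(all_genes) == 0L) integer(0) else rowSums(flags)
  df <- data.frame(gene = all_genes, n_criteria_hit = as.integer(n_hit),
                   stringsAsFactors = FALSE)
  if (length(all_genes) > 0L) {
    df <- cbind(df, as.data.frame(flags))
    names(df)[-(1:2)] <- paste0("criterion_", names(crit))
  } else {
    for (nm in paste0("criterion_", names(crit))) df[[nm]] <- logical(0)
  }
  stopifnot(setequal(df$gene, Reduce(union, crit, character(0))))
  df <- df[df$n_criteria_hit >= min_criteria, , drop = FALSE]
  df <- df[order(-df$n_criteria_hit, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  structure(
    list(criteria_sets = crit, priority_genes = df, matrix = matrix,
         manifest = manifest),
    class = "priority_report"
  )
}

#' @export
print.priority_report <- function(x, ...) {
  cat("Priority report:", nrow(x$priority_genes), "top-priority genes\n")
  sizes <- vapply(x$criteria_sets, length, integer(1))
  cat("Criteria set sizes:",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n")
  if (nrow(x$priority_genes) > 0L) {
    cat("Genes:", paste(x$priority_genes$gene, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.priority_report <- function(object, ...) {
  df <- object$priority_genes
  cat("Top-priority candidate genes:", nrow(df), "\n")
  cat("Evidence matrix:", nrow(object$matrix), "genes x",
      ncol(object$matrix) - 1L, "flags\n\n")
  for (nm in names(object$criteria_sets)) {
    s <- object$criteria_sets[[nm]]
    cat(sprintf("  (%s) n = %-3d %s\n", nm, length(s),
                paste(s, collapse = ", ")))
  }
  if (nrow(df) > 0L) {
    cat("\nRanking (n criteria satisfied):\n")
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-10s %d\n", df$gene[i], df$n_criteria_hit[i]))
    }
  }
  invisible(object)
}

#' @export
as.data.frame.priority_report <- function(x, ...) x$priority_genes

#' @export
plot.priority_report <- function(x, ...) {
  df <- x$priority_genes
  if (nrow(df) == 0L) {
    stop("empty priority report: nothing to plot", call. = FALSE)
  }
  op <- graphics::par(mar = c(4, 7, 2, 1))
  on.exit(graphics::par(op))
  ord <- order(df$n_criteria_hit, rev(seq_len(nrow(df))))
  graphics::barplot(df$n_criteria_hit[ord], names.arg = df$gene[ord],
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "criteria satisfied",
                    main = "Top-priority candidate genes", ...)
  invisible(x)
}

#' One-call prioritization from evidence pools
#'
#' Convenience wrapper: builds the evidence matrix from the input pools and
#' returns the ranked [priority_report()].
#'
#' @inheritParams build_evidence_matrix
#' @inheritParams priority_report
#' @return a \code{priority_report}.
#' @export
prioritize_candidates <- function(candidate_deg_pool, candidate_ur_pool,
                                  recurrent_ge2, recurrent_ge3,
                                  placement_union, lit_top_sets,
                                  min_criteria = 1L, manifest = list()) {
  m <- build_evidence_matrix(candidate_deg_pool, candidate_ur_pool,
                             recurrent_ge2, recurrent_ge3,
                             placement_union, lit_top_sets)
  priority_report(m, min_criteria = min_criteria, manifest = manifest)
}
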