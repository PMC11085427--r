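# Domain containers: study gene sets, pathway collections, regulator networks.

#' Construct a study gene set
#'
#' Holds one study's differentially expressed genes (DEGs) as a normalized,
#' deduplicated symbol set, with optional per-gene direction (+1 up, -1 down).
#' Duplicate symbols collapse to one member; when duplicates disagree on
#' direction the direction is dropped for that gene and a warning is issued
#' (microarray probes map many-to-one onto genes, so this is routine).
#'
#' @param study_id short label, e.g. \code{"P1"}.
#' @param genes character vector of gene symbols (normalized internally).
#' @param direction optional numeric vector in \{-1, 1\} parallel to
#'   \code{genes}, or a named vector keyed by symbol.
#' @param description free-text description.
#' @param alias_map alias map for normalization (see [normalize_symbol()]).
#' @return object of class \code{study_gene_set} with elements
#'   \code{study_id}, \code{description}, \code{genes} (sorted unique),
#'   \code{direction} (named, subset of genes), \code{n_degs}.
#' @export
study_gene_set <- function(study_id, genes, direction = NULL,
                           description = "", alias_map = default_alias_map()) {
  stopifnot(is.character(study_id), length(study_id) == 1L, nzchar(study_id))
  norm <- normalize_symbol(genes, alias_map)
  dir_map <- NULL
  if (!is.null(direction)) {
    if (is.null(names(direction))) {
      if (length(direction) != length(genes)) {
        stop("direction must be named or parallel to genes", call. = FALSE)
      }
      names(direction) <- norm
    } else {
      names(direction) <- normalize_symbol(names(direction), alias_map)
    }
    direction <- direction[!is.na(direction)]
    if (!all(direction %in% c(-1, 1))) {
      stop("direction values must be +1 or -1", call. = FALSE)
    }
    # collapse duplicates: consistent -> keep, conflicting -> unset + warn
    spl <- split(unname(direction), names(direction))
    keep <- vapply(spl, function(v) length(unique(v)) == 1L, logical(1))
    if (any(!keep)) {
      warning("conflicting directions for ", sum(!keep),
              " gene(s); direction unset for: ",
              paste(sort(names(spl)[!keep]), collapse = ", "), call. = FALSE)
    }
    dir_map <- vapply(spl[keep], `[[`, numeric(1), 1L)
  }
  uniq <- sort(unique(norm))
  if (!is.null(dir_map)) dir_map <- dir_map[names(dir_map) %in% uniq]
  structure(
    list(study_id = study_id, description = description, genes = uniq,
         direction = dir_map, n_degs = length(uniq)),
    class = "study_gene_set"
  )
}

#' @export
print.study_gene_set <- function(x, ...) {
  cat("Study gene set '", x$study_id, "': ", x$n_degs, " genes", sep = "")
  if (!is.null(x$direction)) cat(" (", length(x$direction), " with direction)", sep = "")
  cat("\n")
  invisible(x)
}

#' Construct a gene-set collection
#'
#' Named pathway sets with a source tag (\code{KEGG}, \code{WikiPathways},
#' \code{both}, or \code{other}) and an optional thematic category carried
#' from the collection file.
#'
#' @param sets list of lists with elements \code{set_id}, \code{name},
#'   \code{source_tag}, \code{genes}, and optional \code{category}.
#' @param universe optional character vector of background genes; defaults to
#'   the union of all member genes at use time.
#' @return object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  ids <- vapply(sets, `[[`, character(1), "set_id")
  if (anyDuplicated(ids)) {
    stop("duplicate set_id in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  tags <- table(vapply(x$sets, `[[`, character(1), "source_tag"))
  cat("Gene-set collection:", length(x$sets), "sets (",
      paste(names(tags), tags, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Union of member genes of a collection
#' @param collection a [gene_set_collection()].
#' @return sorted character vector.
#' @export
collection_universe <- function(collection) {
  if (!is.null(collection$universe)) return(sort(unique(collection$universe)))
  sort(unique(unlist(lapply(collection$sets, `[[`, "genes"), use.names = FALSE)))
}

#' Construct a regulator network
#'
#' Directed regulator -> target edges with optional sign. Duplicate
#' (regulator, target) pairs are collapsed.
#'
#' @param regulator,target character vectors of gene symbols.
#' @param sign optional numeric vector in \{-1, 1\}.
#' @param alias_map alias map for normalization.
#' @return object of class \code{regulator_network}: data frame of edges plus
#'   a regulator index.
#' @export
regulator_network <- function(regulator, target, sign = NULL,
                              alias_map = default_alias_map()) {
  stopifnot(length(regulator) == length(target))
  reg <- normalize_symbol(regulator, alias_map)
  tgt <- normalize_symbol(target, alias_map)
  edges <- data.frame(regulator = reg, target = tgt,
                      stringsAsFactors = FALSE)
  if (!is.null(sign)) {
    stopifnot(length(sign) == length(regulator), all(sign %in% c(-1, 1)))
    edges$sign <- sign
  }
  edges <- edges[!duplicated(edges[c("regulator", "target")]), , drop = FALSE]
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 targets_by_regulator = split(edges$target, edges$regulator)),
            class = "regulator_network")
}

#' @export
print.regulator_network <- function(x, ...) {
  cat("Regulator network:", nrow(x$edges), "edges,",
      length(x$targets_by_regulator), "regulators\n")
  invisible(x)
}
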