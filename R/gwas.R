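# Curation of GWAS-Catalog-style association exports into trait gene sets.

#' Read a GWAS-Catalog-style association export
#'
#' Tab-delimited export with a header row. Column names are configurable to
#' absorb dialect drift across catalog versions.
#'
#' @param path export file.
#' @param trait_col,gene_col,snp_col,accession_col,pvalue_col column names.
#' @param sep field separator.
#' @return data frame with normalized column names \code{accession},
#'   \code{trait}, \code{rsid}, \code{mapped_gene_raw}, \code{p_value}.
#' @export
read_gwas_export <- function(path, trait_col = "DISEASE/TRAIT",
                             gene_col = "MAPPED_GENE", snp_col = "SNPS",
                             accession_col = "STUDY ACCESSION",
                             pvalue_col = "P-VALUE", sep = "\t") {
  df <- read_delim_table(path, sep)
  need <- c(trait_col, gene_col, snp_col, accession_col)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("GWAS export missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    accession = trimws(as.character(df[[accession_col]])),
    trait = trimws(as.character(df[[trait_col]])),
    rsid = trimws(as.character(df[[snp_col]])),
    mapped_gene_raw = as.character(df[[gene_col]]),
    stringsAsFactors = FALSE
  )
  out$p_value <- if (pvalue_col %in% names(df)) {
    suppressWarnings(as.numeric(df[[pvalue_col]]))
  } else NA_real_
  if (any(!nzchar(out$accession)) || any(!nzchar(out$trait))) {
    stop("GWAS export rows must carry accession and trait", call. = FALSE)
  }
  out
}

#' Parse a mapped-gene field into gene symbols
#'
#' GWAS Catalog mapped-gene strings pack several genes into one cell. The
#' field is split on the separators \code{" - "}, \code{";"}, \code{","},
#' and \code{" x "} (SNP-by-SNP interaction rows contribute genes from both
#' sides); parenthesized \code{"(also GENE)"} annotations are unpacked.
#' Tokens matching the configured non-gene markers (intergenic placeholders,
#' "no mapped genes") are dropped, and survivors are normalized. An empty set
#' is a valid result.
#'
#' @param raw character vector of mapped-gene field values.
#' @param non_gene_markers lowercase markers dropped after splitting.
#' @param alias_map alias map for normalization.
#' @return sorted character vector of unique symbols (pooled over \code{raw}).
#' @examples
#' parse_mapped_genes("APOE - APOC1")
#' parse_mapped_genes("no mapped genes x MYO6")
#' @export
parse_mapped_genes <- function(raw,
                               non_gene_markers = c("no mapped genes",
                                                    "intergenic", "nr", "none"),
                               alias_map = default_alias_map()) {
  if (length(raw) == 0L) return(character(0))
  raw <- as.character(raw)
  raw[is.na(raw)] <- ""
  # unpack "GENE (also OTHER)" and strip emphasis markers
  txt <- gsub("\\(also\\s+", ", ", raw, ignore.case = TRUE)
  txt <- gsub("[)*]", "", txt)
  tokens <- unlist(strsplit(txt, "\\s+-\\s+|;|,|\\s+x\\s+"), use.names = FALSE)
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  # interaction rows carry "rs...; A" allele tokens: drop rs ids and
  # single-letter allele tokens as non-gene content
  tokens <- tokens[!grepl("^rs[0-9]+$", tokens)]
  tokens <- tokens[nchar(tokens) > 1L]
  tokens <- tokens[!tolower(tokens) %in% tolower(non_gene_markers)]
  if (length(tokens) == 0L) return(character(0))
  sort(unique(normalize_symbol(tokens, alias_map)))
}

#' Filter associations by trait keywords
#'
#' Keeps rows whose trait contains at least one include term and none of the
#' exclude terms (case-insensitive substring matching, as the trait
#' refinements are described verbally). Row order is preserved, so the filter
#' is idempotent.
#'
#' @param associations data frame from [read_gwas_export()].
#' @param include_terms character vector, must be non-empty.
#' @param exclude_terms character vector (may be empty).
#' @return filtered data frame.
#' @export
filter_associations <- function(associations, include_terms,
                                exclude_terms = character(0)) {
  if (length(include_terms) == 0L || all(!nzchar(include_terms))) {
    stop("include_terms must be non-empty", call. = FALSE)
  }
  trait <- tolower(associations$trait)
  inc <- Reduce(`|`, lapply(tolower(include_terms),
                            function(t) grepl(t, trait, fixed = TRUE)))
  exc <- if (length(exclude_terms) == 0L) rep(FALSE, length(trait)) else {
    Reduce(`|`, lapply(tolower(exclude_terms),
                       function(t) grepl(t, trait, fixed = TRUE)))
  }
  associations[inc & !exc, , drop = FALSE]
}

#' Build a trait gene set from filtered associations
#'
#' Pools all genes parsed from the mapped-gene field across rows, attaching
#' per-gene provenance (accession, rsid pairs).
#'
#' @param filtered data frame of associations sharing one trait scope.
#' @param trait_label one of \code{hypertension}, \code{atherosclerosis},
#'   \code{arterial_stiffness}, or another label.
#' @param alias_map alias map for normalization.
#' @return object of class \code{trait_gene_set}: \code{trait_label},
#'   \code{genes} (sorted), \code{provenance} (per-gene data frame of
#'   accession/rsid), \code{n_associations}.
#' @export
build_trait_gene_set <- function(filtered, trait_label,
                                 alias_map = default_alias_map()) {
  prov <- list()
  if (nrow(filtered) == 0L) {
    warning("no associations for trait '", trait_label, "'", call. = FALSE)
  }
  for (i in seq_len(nrow(filtered))) {
    genes_i <- parse_mapped_genes(filtered$mapped_gene_raw[i],
                                  alias_map = alias_map)
    for (g in genes_i) {
      prov[[g]] <- rbind(prov[[g]],
                         data.frame(accession = filtered$accession[i],
                                    rsid = filtered$rsid[i],
                                    trait_label = trait_label,
                                    stringsAsFactors = FALSE))
    }
  }
  prov <- lapply(prov, unique)
  structure(
    list(trait_label = trait_label, genes = sort(names(prov)),
         provenance = prov[sort(names(prov))],
         n_associations = nrow(filtered)),
    class = "trait_gene_set"
  )
}

#' @export
print.trait_gene_set <- function(x, ...) {
  cat("Trait gene set '", x$trait_label, "': ", length(x$genes),
      " genes from ", x$n_associations, " associations\n", sep = "")
  invisible(x)
}

#' Union of trait gene sets
#'
#' Pools several trait gene sets into one (default label
#' \code{"vascular_dysfunction"}), merging provenance so that per-trait
#' membership is preserved for downstream trait breakdowns.
#'
#' @param trait_sets list of [build_trait_gene_set()] results (>= 1).
#' @param label label for the pooled set.
#' @return a \code{trait_gene_set}; element \code{per_trait} maps each input
#'   trait label to its gene vector.
#' @export
union_trait_sets <- function(trait_sets, label = "vascular_dysfunction") {
  stopifnot(length(trait_sets) >= 1L)
  prov <- list()
  for (ts in trait_sets) {
    for (g in ts$genes) prov[[g]] <- rbind(prov[[g]], ts$provenance[[g]])
  }
  prov <- lapply(prov, unique)
  out <- structure(
    list(trait_label = label, genes = sort(names(prov)),
         provenance = prov[sort(names(prov))],
         n_associations = sum(vapply(trait_sets, `[[`, numeric(1),
                                     "n_associations"))),
    class = "trait_gene_set"
  )
  out$per_trait <- stats::setNames(
    lapply(trait_sets, `[[`, "genes"),
    vapply(trait_sets, `[[`, character(1), "trait_label")
  )
  out
}

#' Bundled trait-exclusion terms
#'
#' Exclusion phrases used when curating hypertension and atherosclerosis
#' associations (e.g. pulmonary arterial hypertension, preeclampsia), shipped
#' as editable one-phrase-per-line files.
#'
#' @param trait \code{"hypertension"} or \code{"atherosclerosis"}.
#' @return character vector of exclusion phrases.
#' @export
default_exclude_terms <- function(trait = c("hypertension", "atherosclerosis")) {
  trait <- match.arg(trait)
  path <- flavoprior_extdata(paste0(trait, "_exclude_terms.txt"))
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines)]
}
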