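# Accessors for the curated evidence bundled with the package: gene lists
# transcribed from published flavonoid-vascular intervention evidence (five
# peripheral-blood transcriptomic studies), GWAS vascular-trait curation, a
# canonical-pathway placement table, literature counts, and variant
# frequency tables.

#' Bundled per-study candidate upstream-regulator lists
#'
#' The candidate URs (upstream regulators that are also GWAS
#' vascular-dysfunction genes) for each of the five source studies, one list
#' per study, as published.
#'
#' @return named list (\code{P1}..\code{P5}) of sorted gene vectors.
#' @export
bundled_ur_candidates <- function() {
  stats::setNames(
    lapply(1:5, function(i) {
      read_gene_list(flavoprior_extdata(sprintf("ur_candidates_study%d.txt", i)))
    }),
    paste0("P", 1:5)
  )
}

#' Bundled canonical-pathway placement collection
#'
#' The curated KEGG/WikiPathways placement table of candidate DEGs in
#' pathways relevant to vascular dysfunction, as a GMT-backed gene-set
#' collection. Source tags follow the published legend (KEGG, WikiPathways,
#' or both); the category field carries the thematic block (vascular,
#' inflammation, signaling, antioxidant), which is manual curation carried
#' through from the source, not computed.
#'
#' @return a [gene_set_collection()] of 35 sets.
#' @export
bundled_pathways <- function() {
  read_gmt(flavoprior_extdata("pathway_placements.gmt"))
}

#' Bundled recurrent candidate-DEG list
#'
#' Candidate DEGs (DEG x GWAS genes) shared by at least two of the five
#' source studies (15 genes), and the single gene shared by at least three
#' studies.
#'
#' @return list with \code{ge2} (15 genes) and \code{ge3} (1 gene).
#' @export
bundled_recurrent_candidates <- function() {
  list(
    ge2 = read_gene_list(flavoprior_extdata("recurrent_candidate_degs.txt")),
    ge3 = read_gene_list(flavoprior_extdata("multi_study_core_degs.txt"))
  )
}

#' Bundled literature-count table
#'
#' Publication counts for candidate genes from two title/abstract query
#' families: gene AND (SNP OR polymorphism) AND (cardiovascular OR
#' atherosclerosis) (\code{cvd_snp}), and gene AND SNP AND (nutrition OR
#' nutrient OR diet) (\code{nutrition_snp}); counted separately for the
#' candidate-DEG and candidate-UR pools. Counts are a snapshot (literature
#' counts drift with time); regenerate with the same query wording to update.
#' One symbol in the source table is an alias resolved by the bundled alias
#' map.
#'
#' @return a [literature_counts()] table with a \code{pool} column.
#' @export
bundled_literature_counts <- function() {
  read_literature_counts(flavoprior_extdata("literature_counts.tsv"))
}

#' Bundled variant-frequency records
#'
#' Top population-frequency variants for a subset of the top-priority genes
#' (ALDH2, APOE, TNF), transcribed from public variant-browser exports:
#' enough to exercise and document the ranking rules. Full tables for other
#' genes follow the same layout.
#'
#' @return data frame from [read_variant_table()].
#' @export
bundled_variants <- function() {
  read_variant_table(flavoprior_extdata("variant_frequencies.tsv"))
}

#' Bundled GWAS association rows
#'
#' GWAS-Catalog-style association rows for the top-priority genes (accession,
#' trait, rsID, mapped-gene field), useful as a worked curation example and
#' for exercising the mapped-gene parser on real field formats (multi-gene
#' cells, SNP x SNP interaction rows).
#'
#' @return data frame from [read_gwas_export()].
#' @export
bundled_gwas_associations <- function() {
  read_gwas_export(flavoprior_extdata("gwas_vascular_associations.tsv"))
}

#' Bundled candidate-DEG evidence pool
#'
#' The candidate-DEG evidence reconstructible from the published gene lists:
#' the union of the recurrent candidate DEGs, the pathway-placement gene
#' union, and the top-literature DEG sets. (The full 106-gene candidate-DEG
#' pool requires the source studies' supplementary DEG lists; see
#' [read_supplementary_degs()].)
#'
#' @return sorted character vector.
#' @export
bundled_candidate_deg_pool <- function() {
  rec <- bundled_recurrent_candidates()
  placement <- placement_table(collection_universe(bundled_pathways()),
                               bundled_pathways(), min_hits = 2L)
  lit <- bundled_literature_counts()
  thr <- default_literature_thresholds()
  deg_thr <- thr[thr$pool == "deg", , drop = FALSE]
  deg_lit <- unlist(lapply(seq_len(nrow(deg_thr)), function(i) {
    top_genes(lit, deg_thr$category[i], min_count = deg_thr$min_count[i],
              pool = "deg")
  }), use.names = FALSE)
  sort(unique(c(rec$ge2, rec$ge3, placement_gene_union(placement), deg_lit)))
}

#' Run the prioritization on the bundled curated evidence
#'
#' End-to-end reproduction of the prioritization from the bundled evidence
#' lists: pools the per-study candidate URs, builds the pathway placement
#' union, selects top-literature sets, assembles the evidence matrix, and
#' evaluates the six criteria. With the bundled inputs this yields the
#' published 20-gene top-priority set.
#'
#' @param min_criteria passed to [priority_report()].
#' @return a [priority_report()]; the manifest records the input sizes.
#' @export
bundled_prioritization <- function(min_criteria = 1L) {
  ur_lists <- bundled_ur_candidates()
  gwas_pool <- sort(unique(unlist(ur_lists, use.names = FALSE)))
  urs <- candidate_urs(ur_lists, gwas_pool)
  collection <- bundled_pathways()
  placement <- placement_table(collection_universe(collection), collection,
                               min_hits = 2L)
  rec <- bundled_recurrent_candidates()
  lit <- top_literature_sets(bundled_literature_counts())
  deg_pool <- bundled_candidate_deg_pool()
  prioritize_candidates(
    candidate_deg_pool = deg_pool,
    candidate_ur_pool = urs$pooled,
    recurrent_ge2 = rec$ge2,
    recurrent_ge3 = rec$ge3,
    placement_union = placement_gene_union(placement),
    lit_top_sets = lit$sets,
    min_criteria = min_criteria,
    manifest = list(
      n_candidate_degs = length(deg_pool),
      n_candidate_urs = length(urs$pooled),
      ur_per_study = vapply(urs$per_study, length, integer(1)),
      n_pathways = length(collection$sets),
      placement_union = length(placement_gene_union(placement))
    )
  )
}
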