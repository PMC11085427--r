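# Synthetic-data generator with planted ground truth. Every pipeline stage
# can be exercised offline: studies with a shared recurrent core, a
# GWAS-style association export with decoy traits, pathway collections and
# regulator networks with planted enrichment, and heavy-tailed literature
# counts.

# One documented pseudo-random stream per generator stage: the stage seed is
# derived from (seed, stage name) so stages never share a stream and adding a
# stage never shifts another stage's draws. The derivation scrambles the user
# seed through two multiplicative congruential steps (L'Ecuyer multipliers;
# every product stays below 2^53, so the double arithmetic is exact) to keep
# the streams of nearby user seeds decorrelated.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  s <- (abs(as.double(seed)) + 1664525 * h) %% 2147483563
  s <- (40014 * s) %% 2147483563
  s <- (40692 * ((s + h) %% 2147483399)) %% 2147483399
  as.integer(s)
}

#' Default synthetic-generation parameters
#'
#' Mirrors the magnitudes of the study conditions the pipeline targets: five
#' studies with DEG-list sizes 1693/717/554/2231/1401 over a 20,000-gene
#' universe, a shared recurrent core, GWAS trait sets of 375/69/58 genes, a
#' pathway collection and regulator network with planted signal, and planted
#' priority genes placed to satisfy the prioritization criteria.
#'
#' @param universe_size number of genes in the universe.
#' @param study_sizes integer vector of per-study DEG counts.
#' @param shared_core_size genes present in every study.
#' @param trait_sizes named vector of GWAS trait gene-set sizes.
#' @param trait_deg_overlap fraction of each trait set drawn from the DEG
#'   union (0..1); drives the size of the candidate pools.
#' @param n_planted_priority planted priority genes (placed in >= 2 studies,
#'   every trait set, planted pathways/regulators, and literature top sets).
#' @param n_pathways,pathway_size background pathway collection shape.
#' @param n_planted_pathways,pathway_enrichment planted pathways and the
#'   factor by which they oversample DEGs (1 = null).
#' @param n_regulators,targets_per_regulator background network shape.
#' @param n_planted_regulators,regulator_bias planted regulators and their
#'   DEG-target oversampling factor (1 = null).
#' @param lit_threshold count that separates planted top-literature genes
#'   from the geometric-tail background.
#' @return list of parameters.
#' @export
synthetic_params <- function(universe_size = 20000L,
                             study_sizes = c(1693L, 717L, 554L, 2231L, 1401L),
                             shared_core_size = 60L,
                             trait_sizes = c(hypertension = 375L,
                                             atherosclerosis = 69L,
                                             arterial_stiffness = 58L),
                             trait_deg_overlap = 0.25,
                             n_planted_priority = 8L,
                             n_pathways = 40L, pathway_size = 30L,
                             n_planted_pathways = 3L,
                             pathway_enrichment = 5,
                             n_regulators = 80L,
                             targets_per_regulator = 40L,
                             n_planted_regulators = 4L,
                             regulator_bias = 5,
                             lit_threshold = 30L) {
  p <- as.list(environment())
  stopifnot(p$shared_core_size <= min(p$study_sizes),
            all(p$trait_sizes <= p$universe_size),
            p$pathway_enrichment >= 1, p$regulator_bias >= 1)
  p
}

synthetic_universe <- function(params) {
  sprintf("G%05d", seq_len(params$universe_size))
}

# Planted entities are carved deterministically from the front of the
# universe so that every stage agrees on them without sharing random streams.
planted_priority_genes <- function(params) {
  synthetic_universe(params)[seq_len(params$n_planted_priority)]
}

#' Generate synthetic study gene sets
#'
#' Each study is the shared core (drawn once), plus the planted priority
#' genes (each placed in at least two studies), plus an independent uniform
#' draw up to the study's target size. With \code{shared_core_size = 0} and
#' no planted genes, pairwise overlaps follow the uniform expectation
#' n_i n_j / universe_size.
#'
#' @param params from [synthetic_params()].
#' @param seed integer seed; generation is a pure function of
#'   (params, seed).
#' @return list of [study_gene_set()] objects (\code{S1}..).
#' @export
generate_studies <- function(params = synthetic_params(), seed = 1L) {
  if (params$shared_core_size > min(params$study_sizes)) {
    stop("shared core larger than smallest study", call. = FALSE)
  }
  set.seed(stage_seed(seed, "studies"))
  universe <- synthetic_universe(params)
  planted <- planted_priority_genes(params)
  core_pool <- setdiff(universe, planted)
  core <- sample(core_pool, params$shared_core_size)
  k <- length(params$study_sizes)
  # each planted gene lands in >= 2 studies
  planted_studies <- lapply(planted, function(g) sample(k, 2L))
  studies <- vector("list", k)
  for (i in seq_len(k)) {
    base <- c(core, planted[vapply(planted_studies,
                                   function(s) i %in% s, logical(1))])
    extra_n <- params$study_sizes[i] - length(base)
    if (extra_n < 0L) stop("infeasible study size", call. = FALSE)
    extra <- sample(setdiff(universe, base), extra_n)
    studies[[i]] <- study_gene_set(paste0("S", i), c(base, extra),
                                   alias_map = NULL)
  }
  studies
}

#' Generate a synthetic GWAS association export
#'
#' Draws per-trait gene sets (part from the DEG union at rate
#' \code{trait_deg_overlap}, the planted priority genes always included;
#' remainder uniform from the non-DEG universe) and wraps them in the
#' association-export dialect, one row per gene with a synthetic accession
#' and rsID. Decoy rows carrying excluded trait phrasings (e.g.
#' "preeclampsia", "pulmonary arterial hypertension") are appended so the
#' default trait filter always has something to remove.
#'
#' @param params from [synthetic_params()].
#' @param seed integer seed.
#' @param studies optional study list from [generate_studies()] (regenerated
#'   from the same seed when omitted).
#' @param overlap override for \code{trait_deg_overlap}; 0 keeps planted and
#'   DEG genes out of the trait sets entirely.
#' @return data frame in [read_gwas_export()]'s normalized layout; attribute
#'   \code{truth} records the per-trait gene draws.
#' @export
generate_gwas <- function(params = synthetic_params(), seed = 1L,
                          studies = NULL, overlap = params$trait_deg_overlap) {
  if (is.null(studies)) studies <- generate_studies(params, seed)
  set.seed(stage_seed(seed, "gwas"))
  universe <- synthetic_universe(params)
  deg_union <- sort(unique(unlist(lapply(studies, `[[`, "genes"),
                                  use.names = FALSE)))
  planted <- if (overlap > 0) planted_priority_genes(params) else character(0)
  rows <- list()
  truth <- list()
  acc_i <- 0L
  for (trait in names(params$trait_sizes)) {
    size <- params$trait_sizes[[trait]]
    n_deg <- min(length(deg_union), max(length(planted),
                                        round(overlap * size)))
    from_deg <- if (n_deg > 0) {
      unique(c(planted, sample(setdiff(deg_union, planted),
                               max(0L, n_deg - length(planted)))))
    } else character(0)
    pool <- setdiff(universe, deg_union)
    genes <- c(from_deg, sample(pool, size - length(from_deg)))
    truth[[trait]] <- sort(genes)
    acc_i <- acc_i + 1L
    trait_label <- gsub("_", " ", trait)
    rows[[trait]] <- data.frame(
      accession = sprintf("GCST9%06d", acc_i * 1000L + seq_along(genes)),
      trait = trait_label,
      rsid = sprintf("rs%d", sample(1e6, length(genes))),
      mapped_gene_raw = genes,
      p_value = signif(10^-stats::runif(length(genes), 8, 20), 3),
      stringsAsFactors = FALSE
    )
  }
  decoys <- data.frame(
    accession = sprintf("GCST8%06d", 1:3),
    trait = c("pulmonary arterial hypertension", "preeclampsia",
              "treatment-resistant hypertension"),
    rsid = sprintf("rs%d", sample(1e6, 3)),
    mapped_gene_raw = sample(universe, 3),
    p_value = 1e-9,
    stringsAsFactors = FALSE
  )
  out <- rbind(do.call(rbind, rows), decoys)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic pathway collection and regulator network
#'
#' Background pathway sets and regulator target lists are uniform draws from
#' the universe. Planted pathways and regulators oversample the DEG union by
#' the configured factor (weighted sampling without replacement; factor 1
#' reproduces the null). Planted priority genes are always members of the
#' planted pathways and targets of the planted regulators.
#'
#' @param params from [synthetic_params()].
#' @param seed integer seed.
#' @param studies optional study list (regenerated from seed when omitted).
#' @return list with \code{collection} ([gene_set_collection()]),
#'   \code{network} ([regulator_network()]), and \code{truth} (planted
#'   pathway set_ids and regulator names).
#' @export
generate_collection_and_network <- function(params = synthetic_params(),
                                            seed = 1L, studies = NULL) {
  if (is.null(studies)) studies <- generate_studies(params, seed)
  set.seed(stage_seed(seed, "collection"))
  universe <- synthetic_universe(params)
  deg_union <- unique(unlist(lapply(studies, `[[`, "genes"),
                             use.names = FALSE))
  planted <- planted_priority_genes(params)
  weights_for <- function(factor) {
    w <- rep(1, length(universe))
    w[universe %in% deg_union] <- factor
    w
  }
  draw_set <- function(size, factor, force = character(0)) {
    force <- unique(force)
    pool <- setdiff(universe, force)
    w <- weights_for(factor)[match(pool, universe)]
    c(force, sample(pool, size - length(force), prob = w))
  }
  n_planted <- params$n_planted_pathways
  sets <- vector("list", params$n_pathways)
  for (i in seq_len(params$n_pathways)) {
    is_planted <- i <= n_planted
    sets[[i]] <- list(
      set_id = sprintf("PW%03d", i),
      name = sprintf("PW%03d", i),
      source_tag = if (i %% 2L == 0L) "KEGG" else "WikiPathways",
      category = if (is_planted) "planted" else "background",
      genes = sort(draw_set(params$pathway_size,
                            if (is_planted) params$pathway_enrichment else 1,
                            force = if (is_planted) planted else character(0)))
    )
  }
  set.seed(stage_seed(seed, "network"))
  regs <- sprintf("REG%03d", seq_len(params$n_regulators))
  edges_reg <- character(0)
  edges_tgt <- character(0)
  for (i in seq_len(params$n_regulators)) {
    is_planted <- i <= params$n_planted_regulators
    tgt <- draw_set(params$targets_per_regulator,
                    if (is_planted) params$regulator_bias else 1,
                    force = if (is_planted) planted else character(0))
    edges_reg <- c(edges_reg, rep(regs[i], length(tgt)))
    edges_tgt <- c(edges_tgt, tgt)
  }
  list(
    collection = gene_set_collection(sets, universe = universe),
    network = regulator_network(edges_reg, edges_tgt, alias_map = NULL),
    truth = list(
      planted_pathways = sprintf("PW%03d", seq_len(n_planted)),
      planted_regulators = regs[seq_len(params$n_planted_regulators)]
    )
  )
}

#' Generate synthetic literature counts
#'
#' Planted priority genes receive counts at or above the configured
#' threshold; background genes draw from a geometric tail (heavy right tail,
#' most genes with a handful of publications). Counts are emitted for both
#' query categories and both pools.
#'
#' @param params from [synthetic_params()].
#' @param seed integer seed.
#' @param genes background genes to count (defaults to a sample of the
#'   universe).
#' @return a [literature_counts()] table with a \code{pool} column.
#' @export
generate_lit_counts <- function(params = synthetic_params(), seed = 1L,
                                genes = NULL) {
  set.seed(stage_seed(seed, "literature"))
  universe <- synthetic_universe(params)
  planted <- planted_priority_genes(params)
  if (is.null(genes)) {
    genes <- sample(setdiff(universe, planted), 200L)
  }
  thr <- params$lit_threshold
  rows <- list()
  for (pool in c("deg", "ur")) {
    for (category in c("cvd_snp", "nutrition_snp")) {
      bg <- stats::rgeom(length(genes), prob = 0.25)
      bg <- pmin(bg, thr - 1L)  # background never crosses the threshold
      pl <- thr + stats::rgeom(length(planted), prob = 0.05)
      rows[[paste(pool, category)]] <- data.frame(
        gene = c(genes, planted), pool = pool, category = category,
        count = c(bg, pl), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  literature_counts(df, alias_map = NULL)
}

#' Generate a complete synthetic input bundle
#'
#' Runs every generator stage under one seed and, optionally, writes the
#' bundle to disk in exactly the formats the ingestion readers accept (study
#' TSVs, association TSV, GMT, network TSV, counts TSV, truth JSON).
#' Identical (params, seed) yield identical bundles, byte for byte.
#'
#' @param params from [synthetic_params()].
#' @param seed integer seed.
#' @param dir optional output directory; when given, files are written and
#'   their paths returned in the result.
#' @return list with \code{studies}, \code{gwas}, \code{collection},
#'   \code{network}, \code{lit_counts}, and \code{truth} (planted genes,
#'   pathways, regulators, parameters, seed).
#' @export
generate_bundle <- function(params = synthetic_params(), seed = 1L,
                            dir = NULL) {
  studies <- generate_studies(params, seed)
  gwas <- generate_gwas(params, seed, studies = studies)
  cn <- generate_collection_and_network(params, seed, studies = studies)
  lit <- generate_lit_counts(params, seed)
  truth <- list(
    planted_priority_genes = planted_priority_genes(params),
    planted_pathways = cn$truth$planted_pathways,
    planted_regulators = cn$truth$planted_regulators,
    trait_genes = attr(gwas, "truth"),
    seed = seed,
    params = params[c("universe_size", "shared_core_size",
                      "trait_deg_overlap", "pathway_enrichment",
                      "regulator_bias", "lit_threshold")]
  )
  bundle <- list(studies = studies, gwas = gwas,
                 collection = cn$collection, network = cn$network,
                 lit_counts = lit, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (s in studies) {
      utils::write.table(data.frame(gene = s$genes),
                         file.path(dir, paste0(tolower(s$study_id), ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    gw <- gwas
    names(gw) <- c("STUDY ACCESSION", "DISEASE/TRAIT", "SNPS",
                   "MAPPED_GENE", "P-VALUE")
    utils::write.table(gw, file.path(dir, "gwas_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gmt_lines <- vapply(cn$collection$sets, function(s) {
      paste(c(s$set_id, paste(s$source_tag, s$category, sep = "|"), s$genes),
            collapse = "\t")
    }, character(1))
    writeLines(gmt_lines, file.path(dir, "pathways.gmt"))
    utils::write.table(cn$network$edges, file.path(dir, "network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(lit), file.path(dir, "lit_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    bundle$paths <- list.files(dir, full.names = TRUE)
  }
  bundle
}
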