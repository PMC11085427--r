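# Configuration-driven pipeline: curation -> recurrence -> integration ->
# pathway placement -> UR intersection -> evidence matrix -> priority set.

#' Validate a pipeline configuration
#'
#' Checks the configuration (a YAML file path or an equivalent named list)
#' before any stage runs: required sections present, referenced paths exist,
#' thresholds in range. Returns the normalized configuration.
#'
#' @param config path to a YAML configuration file, or a named list.
#' @return validated configuration list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  need <- c("studies", "gwas", "pathways", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0L) {
    stop("config missing section(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (s in config$studies) {
    if (is.null(s$path) || !file.exists(s$path)) {
      stop("study table not found: ", s$path %||% "<missing path>",
           call. = FALSE)
    }
    if (is.null(s$study_id)) stop("study entry without study_id", call. = FALSE)
  }
  if (anyDuplicated(vapply(config$studies, `[[`, character(1), "study_id"))) {
    stop("duplicate study_id in config", call. = FALSE)
  }
  if (!file.exists(config$gwas$path %||% "")) {
    stop("GWAS export not found: ", config$gwas$path %||% "<missing path>",
         call. = FALSE)
  }
  if (!file.exists(config$pathways %||% "")) {
    stop("pathway GMT not found: ", config$pathways %||% "<missing path>",
         call. = FALSE)
  }
  for (p in config$ur_lists) {
    if (!file.exists(p)) stop("UR list not found: ", p, call. = FALSE)
  }
  if (!is.null(config$network) && !file.exists(config$network)) {
    stop("network table not found: ", config$network, call. = FALSE)
  }
  if (!is.null(config$lit_counts) && !file.exists(config$lit_counts)) {
    stop("literature count table not found: ", config$lit_counts, call. = FALSE)
  }
  thr <- config$thresholds %||% list()
  thr$min_hits <- thr$min_hits %||% 2L
  thr$ur_q <- thr$ur_q %||% 0.01
  thr$ora_q <- thr$ora_q %||% 0.05
  if (thr$min_hits < 1L || thr$ur_q <= 0 || thr$ur_q > 1 ||
      thr$ora_q <= 0 || thr$ora_q > 1) {
    stop("thresholds out of range", call. = FALSE)
  }
  config$thresholds <- thr
  config$min_criteria <- config$min_criteria %||% 1L
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full prioritization pipeline
#'
#' Executes curation, recurrence, DEG x GWAS integration, pathway placement,
#' UR intersection, and evidence/priority assembly from a single
#' configuration, writing every stage table plus a reproducibility manifest
#' (input checksums, thresholds, package version) to the output directory. A
#' stage failure aborts with an error naming the stage. Re-running with
#' unchanged config and inputs reproduces byte-identical outputs.
#'
#' Configuration sections (YAML or list): \code{studies} (list of
#' \code{path}/\code{study_id}/optional \code{gene_col}), \code{gwas}
#' (\code{path} plus \code{traits}: list of \code{label} /
#' \code{include_terms} / optional \code{exclude_terms}), \code{pathways}
#' (GMT path), optional \code{ur_lists} (named study_id -> path) or
#' \code{network} (edge-table path), optional \code{lit_counts} and
#' \code{lit_thresholds}, \code{thresholds} (\code{min_hits}, \code{ora_q},
#' \code{ur_q}), \code{min_criteria}, \code{alias_map}, \code{out_dir}.
#'
#' @param config YAML path or named list (see [validate_config()]).
#' @return the [priority_report()]; stage outputs on disk under
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  alias_map <- if (!is.null(config$alias_map)) {
    read_alias_map(config$alias_map)
  } else default_alias_map()

  log("stage curate: reading GWAS export")
  trait_sets <- stage("curate", {
    assoc <- read_gwas_export(config$gwas$path)
    traits <- config$gwas$traits %||% list(
      list(label = "hypertension", include_terms = "hypertension",
           exclude_terms = default_exclude_terms("hypertension")),
      list(label = "atherosclerosis", include_terms = "atherosclerosis",
           exclude_terms = default_exclude_terms("atherosclerosis")),
      list(label = "arterial_stiffness", include_terms = "arterial stiffness")
    )
    lapply(traits, function(tr) {
      kept <- filter_associations(assoc, unlist(tr$include_terms),
                                  unlist(tr$exclude_terms %||% character(0)))
      build_trait_gene_set(kept, tr$label, alias_map = alias_map)
    })
  })
  gwas_pool <- union_trait_sets(trait_sets)
  log("stage curate: ", length(gwas_pool$genes), " pooled GWAS genes")

  log("stage venn: reading study tables")
  studies <- stage("venn", {
    lapply(config$studies, function(s) {
      read_study_table(s$path, s$study_id, gene_col = s$gene_col %||% "gene",
                       sep = s$sep %||% "\t", alias_map = alias_map)
    })
  })
  partition <- stage("venn", venn_partition(studies))
  rec2 <- genes_in_at_least(studies, 2L)
  rec3 <- genes_in_at_least(studies, min(3L, length(studies)))

  log("stage integrate: DEG x GWAS")
  cand <- stage("integrate", candidate_degs(studies, trait_sets))
  log("stage integrate: ", length(cand$pooled), " candidate DEGs")

  log("stage enrich: pathway placement")
  enr <- stage("enrich", {
    collection <- read_gmt(config$pathways, alias_map = alias_map)
    list(collection = collection,
         ora = run_ora(cand$pooled, collection),
         placement = placement_table(cand$pooled, collection,
                                     min_hits = config$thresholds$min_hits))
  })

  log("stage urs: candidate upstream regulators")
  ur <- stage("urs", {
    ur_lists <- if (!is.null(config$ur_lists)) {
      lapply(config$ur_lists, read_gene_list, alias_map = alias_map)
    } else if (!is.null(config$network)) {
      network <- read_network_table(config$network, alias_map = alias_map)
      universe <- sort(unique(c(network$edges$target,
                                unlist(lapply(studies, `[[`, "genes"),
                                       use.names = FALSE))))
      scans <- lapply(studies, function(s) {
        res <- ur_overlap_scan(s, network, universe,
                               alpha = config$thresholds$ur_q)
        res$regulator[res$significant]
      })
      stats::setNames(scans, vapply(studies, `[[`, character(1), "study_id"))
    } else {
      stop("neither ur_lists nor network configured")
    }
    candidate_urs(ur_lists, gwas_pool)
  })
  log("stage urs: ", length(ur$pooled), " pooled candidate URs")

  lit_sets <- list()
  if (!is.null(config$lit_counts)) {
    log("stage literature: top evidence sets")
    lit_sets <- stage("literature", {
      counts <- read_literature_counts(config$lit_counts,
                                       alias_map = alias_map)
      thr <- if (!is.null(config$lit_thresholds)) {
        do.call(rbind, lapply(config$lit_thresholds, as.data.frame))
      } else default_literature_thresholds()
      top_literature_sets(counts, thr)$sets
    })
  }

  log("stage prioritize: evidence matrix and criteria")
  report <- stage("prioritize", {
    prioritize_candidates(
      candidate_deg_pool = cand$pooled,
      candidate_ur_pool = ur$pooled,
      recurrent_ge2 = intersect(cand$pooled, rec2),
      recurrent_ge3 = intersect(cand$pooled, rec3),
      placement_union = placement_gene_union(enr$placement),
      lit_top_sets = if (length(lit_sets) > 0L) lit_sets else character(0),
      min_criteria = config$min_criteria
    )
  })
  log("stage prioritize: ", nrow(report$priority_genes), " priority genes")

  inputs <- c(vapply(config$studies, `[[`, character(1), "path"),
              config$gwas$path, config$pathways,
              unlist(config$ur_lists), config$network, config$lit_counts)
  manifest <- list(
    package_version = as.character(utils::packageVersion("flavoprior")),
    thresholds = config$thresholds,
    min_criteria = config$min_criteria,
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(inputs)), basename(inputs))),
    n_candidate_degs = length(cand$pooled),
    n_candidate_urs = length(ur$pooled),
    priority_genes = report$priority_genes$gene
  )
  report$manifest <- manifest

  trait_tab <- do.call(rbind, lapply(trait_sets, function(ts) {
    data.frame(trait = ts$trait_label, gene = ts$genes,
               stringsAsFactors = FALSE)
  }))
  ur_tab <- do.call(rbind, lapply(names(ur$per_study), function(id) {
    if (length(ur$per_study[[id]]) == 0L) return(NULL)
    data.frame(study_id = id, gene = ur$per_study[[id]],
               stringsAsFactors = FALSE)
  })) %||% data.frame(study_id = character(0), gene = character(0))
  write_report(list(
    trait_genes = trait_tab,
    venn_regions = venn_region_table(partition),
    candidate_deg_counts = as.data.frame.table(
      cand$cell_counts, responseName = "n_genes",
      stringsAsFactors = FALSE),
    candidate_degs = data.frame(gene = cand$pooled),
    enrichment = as.data.frame(enr$ora),
    placement = as.data.frame(enr$placement),
    candidate_urs = ur_tab,
    evidence_matrix = as.data.frame(report$matrix),
    priority = report$priority_genes
  ), out_dir, format = "tsv")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(as.data.frame(report$matrix),
                       file.path(out_dir, "evidence_matrix.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  report
}
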