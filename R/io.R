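# Readers and writers for the delimited-text formats the pipeline touches.

read_delim_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    quote = "", comment.char = "", check.names = FALSE,
                    fill = TRUE)
}

#' Read a study DEG table
#'
#' Reads a delimited table holding one study's differentially expressed
#' genes. Only a gene-symbol column is required; an optional direction column
#' (values in \{-1, 1\}, or \code{up}/\code{down}) is carried along.
#'
#' @param path delimited text file with a header row.
#' @param study_id label for the study.
#' @param gene_col,direction_col column names (direction optional; pass
#'   \code{NULL} to ignore).
#' @param sep field separator (tab default, \code{","} accepted).
#' @param alias_map alias map for symbol normalization.
#' @return a [study_gene_set()].
#' @export
read_study_table <- function(path, study_id, gene_col = "gene",
                             direction_col = NULL, sep = "\t",
                             alias_map = default_alias_map()) {
  df <- read_delim_table(path, sep)
  if (!gene_col %in% names(df)) {
    stop("missing gene column '", gene_col, "' in ", path, call. = FALSE)
  }
  genes <- trimws(as.character(df[[gene_col]]))
  keep <- !is.na(genes) & genes != ""
  genes <- genes[keep]
  if (length(genes) == 0L) stop("no genes parsed from ", path, call. = FALSE)
  direction <- NULL
  if (!is.null(direction_col) && direction_col %in% names(df)) {
    d <- df[[direction_col]][keep]
    d <- ifelse(d %in% c("up", "Up", "UP", "1", 1), 1,
                ifelse(d %in% c("down", "Down", "DOWN", "-1", -1), -1, NA))
    direction <- stats::setNames(d, normalize_symbol(genes, alias_map))
    direction <- direction[!is.na(direction)]
    if (length(direction) == 0L) direction <- NULL
  }
  study_gene_set(study_id, genes, direction = direction,
                 description = basename(path), alias_map = alias_map)
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited GMT: set id, description, then member genes. The
#' description field doubles as a source-tag carrier: its first
#' \code{|}-separated token is matched (case-insensitively) against the
#' configured tags (\code{KEGG}, \code{WikiPathways}, \code{both}); anything
#' else is tagged \code{other}. A second token, when present, is kept as a
#' thematic category.
#'
#' @param path GMT file.
#' @param source_tags character vector of recognized source tags.
#' @param alias_map alias map for member-gene normalization.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, source_tags = c("KEGG", "WikiPathways", "both"),
                     alias_map = default_alias_map()) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields in ", path, call. = FALSE)
    }
    desc_tokens <- trimws(strsplit(fields[2L], "|", fixed = TRUE)[[1L]])
    tag_hit <- match(toupper(desc_tokens[1L]), toupper(source_tags))
    sets[[i]] <- list(
      set_id = trimws(fields[1L]),
      name = trimws(fields[1L]),
      source_tag = if (is.na(tag_hit)) "other" else source_tags[tag_hit],
      category = if (length(desc_tokens) >= 2L) desc_tokens[2L] else NA_character_,
      genes = sort(unique(normalize_symbol(fields[-(1:2)], alias_map)))
    )
  }
  gene_set_collection(sets)
}

#' Read a plain gene list (one symbol per line)
#'
#' @param path text file, one symbol per line; blank lines and lines starting
#'   with \code{#} are ignored.
#' @param alias_map alias map for normalization.
#' @return sorted character vector of unique symbols.
#' @export
read_gene_list <- function(path, alias_map = default_alias_map()) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(character(0))
  sort(unique(normalize_symbol(lines, alias_map)))
}

#' Read a regulator-target network table
#'
#' @param path 2-3 column delimited file with header: regulator, target, and
#'   optional sign column.
#' @param sep field separator.
#' @param alias_map alias map for normalization.
#' @return a [regulator_network()].
#' @export
read_network_table <- function(path, sep = "\t",
                               alias_map = default_alias_map()) {
  df <- read_delim_table(path, sep)
  if (ncol(df) < 2L) stop("network table needs >= 2 columns", call. = FALSE)
  if (nrow(df) == 0L) stop("empty network table: ", path, call. = FALSE)
  sign <- if (ncol(df) >= 3L) df[[3L]] else NULL
  regulator_network(df[[1L]], df[[2L]], sign = sign, alias_map = alias_map)
}

#' Read a literature-count table
#'
#' @param path delimited file with columns \code{gene}, \code{category},
#'   \code{count}, and optionally \code{pool} (e.g. \code{deg}/\code{ur}).
#' @param sep field separator.
#' @param alias_map alias map for normalization.
#' @return object of class \code{literature_counts} (a data frame).
#' @export
read_literature_counts <- function(path, sep = "\t",
                                   alias_map = default_alias_map()) {
  df <- read_delim_table(path, sep)
  need <- c("gene", "category", "count")
  if (!all(need %in% names(df))) {
    stop("literature counts need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  literature_counts(df, alias_map = alias_map)
}

#' Construct a literature-counts object
#'
#' @param df data frame with columns \code{gene}, \code{category},
#'   \code{count}, optional \code{pool}.
#' @param alias_map alias map for normalization.
#' @return data frame of class \code{literature_counts}.
#' @export
literature_counts <- function(df, alias_map = default_alias_map()) {
  stopifnot(all(c("gene", "category", "count") %in% names(df)))
  df$gene <- normalize_symbol(df$gene, alias_map)
  df$count <- as.numeric(df$count)
  if (any(is.na(df$count)) || any(df$count < 0)) {
    stop("literature counts must be non-negative numbers", call. = FALSE)
  }
  df <- df[order(df$gene, df$category), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("literature_counts", "data.frame")
  df
}

#' Read a variant-annotation table
#'
#' @param path delimited file with columns \code{gene}, \code{rsid},
#'   \code{consequence}, \code{frequency} (fraction in [0,1], may be empty),
#'   and optional \code{clinical_significance}.
#' @param sep field separator.
#' @param alias_map alias map for normalization.
#' @return data frame of variant records.
#' @export
read_variant_table <- function(path, sep = "\t",
                               alias_map = default_alias_map()) {
  df <- read_delim_table(path, sep)
  need <- c("gene", "rsid", "frequency")
  if (!all(need %in% names(df))) {
    stop("variant table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$gene <- normalize_symbol(df$gene, alias_map)
  df$rsid <- trimws(as.character(df$rsid))
  if (!all(grepl("^rs[0-9]+$", df$rsid))) {
    stop("rsid values must match 'rs<digits>'", call. = FALSE)
  }
  df$frequency <- suppressWarnings(as.numeric(df$frequency))
  ok <- is.na(df$frequency) | (df$frequency >= 0 & df$frequency <= 1)
  if (!all(ok)) stop("frequency values must lie in [0, 1]", call. = FALSE)
  if (!"consequence" %in% names(df)) df$consequence <- NA_character_
  if (!"clinical_significance" %in% names(df)) {
    df$clinical_significance <- NA_character_
  }
  rownames(df) <- NULL
  df
}

#' Read supplementary per-study DEG lists when available
#'
#' The five source studies' full DEG lists live in a supplementary appendix
#' that is not redistributed with the package. When a user has downloaded
#' them as per-study gene lists (one symbol per line, files named
#' \code{study1.txt} ... \code{study5.txt}), this reads them into study gene
#' sets; regression checks that depend on the full lists run only then.
#'
#' @param dir directory holding \code{study<i>.txt} files.
#' @param alias_map alias map for normalization.
#' @return list of [study_gene_set()] objects.
#' @export
read_supplementary_degs <- function(dir, alias_map = default_alias_map()) {
  if (!dir.exists(dir)) {
    stop("supplementary DEG directory not found: ", dir, call. = FALSE)
  }
  files <- file.path(dir, sprintf("study%d.txt", 1:5))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("missing supplementary DEG list(s): ",
         paste(basename(files[missing]), collapse = ", "), call. = FALSE)
  }
  lapply(seq_along(files), function(i) {
    study_gene_set(paste0("P", i), read_gene_list(files[i], alias_map),
                   alias_map = alias_map)
  })
}

#' Write report tables deterministically
#'
#' Writes each table in a named list to \code{out_dir}, one file per table,
#' as TSV or JSON. Rows are written in the order given (callers sort before
#' writing; all package report builders emit alphabetical/defined orders), so
#' identical input yields byte-identical output.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @param format \code{"tsv"} or \code{"json"}.
#' @return invisibly, the vector of file paths written.
#' @export
write_report <- function(tables, out_dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.list(tables), length(tables) > 0L)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list", call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    path <- file.path(out_dir, paste0(nm, ".", format))
    if (format == "tsv") {
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
    } else {
      jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back a report table
#'
#' Round-trip companion to [write_report()].
#'
#' @param path file written by [write_report()].
#' @return data frame.
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, comment.char = "",
                      check.names = FALSE)
  } else if (ext == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    stop("unknown report format: ", ext, call. = FALSE)
  }
}
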