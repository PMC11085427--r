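# Gene-symbol normalization and alias resolution.

#' Normalize gene symbols
#'
#' Trims whitespace, upper-cases, and resolves aliases against an alias map
#' (case-insensitive). HGNC-style symbols are short uppercase tokens; the
#' bundled alias map resolves known variants seen in curated evidence tables
#' (e.g. \code{PPRG} -> \code{PPARG}, \code{IL8} -> \code{CXCL8}).
#'
#' Normalization is idempotent: applying it twice gives the same result,
#' provided the alias map itself maps onto canonical symbols.
#'
#' @param raw character vector of raw symbols.
#' @param alias_map named character vector (names = aliases, values =
#'   canonical symbols), or \code{NULL} for no alias resolution. Defaults to
#'   the bundled map, see [default_alias_map()].
#' @return character vector of normalized symbols.
#' @examples
#' normalize_symbol(c(" pparg ", "PPRG", "tnf"))
#' @export
normalize_symbol <- function(raw, alias_map = default_alias_map()) {
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(trimws(raw))
  bad <- is.na(out) | out == ""
  if (any(bad)) {
    stop("invalid gene symbol: empty or missing after trimming (",
         sum(bad), " value(s))", call. = FALSE)
  }
  if (!is.null(alias_map) && length(alias_map) > 0L) {
    lookup <- toupper(trimws(unname(alias_map)))
    names(lookup) <- toupper(trimws(names(alias_map)))
    hit <- match(out, names(lookup))
    out[!is.na(hit)] <- lookup[hit[!is.na(hit)]]
  }
  out
}

#' Bundled gene-symbol alias map
#'
#' Reads the two-column alias file shipped with the package
#' (\code{extdata/curated/alias_map.tsv}). Users may edit a copy and pass it
#' through [read_alias_map()].
#'
#' @return named character vector mapping alias -> canonical symbol.
#' @export
default_alias_map <- function() {
  read_alias_map(flavoprior_extdata("alias_map.tsv"))
}

#' Read an alias map file
#'
#' @param path two-column delimited file with header \code{alias<TAB>symbol}.
#' @param sep field separator (default tab).
#' @return named character vector mapping alias -> canonical symbol.
#' @export
read_alias_map <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("alias map needs two columns (alias, symbol)", call. = FALSE)
  stats::setNames(toupper(trimws(df[[2L]])), toupper(trimws(df[[1L]])))
}

# Path helper for bundled curated evidence files.
flavoprior_extdata <- function(file) {
  p <- system.file("extdata", "curated", file, package = "flavoprior")
  if (p == "") stop("bundled file not found: ", file, call. = FALSE)
  p
}
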