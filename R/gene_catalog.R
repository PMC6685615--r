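# Keyword lists and the packaged RAS-superfamily gene-symbol catalog.

#' Construct a keyword list
#'
#' @param entries Character vector of keywords, order preserved.
#' @param name Label for the list.
#' @return An object of class `keyword_list` with elements `entries`,
#'   `name` and `normalized` (uppercased, deduplicated, empties dropped).
#' @export
keyword_list <- function(entries, name = "keywords") {
  entries <- as.character(entries)
  entries <- trimws(entries)
  entries <- entries[nzchar(entries)]
  structure(
    list(entries = entries, name = name,
         normalized = unique(toupper(entries))),
    class = "keyword_list"
  )
}

#' @export
print.keyword_list <- function(x, ...) {
  cat("<keyword_list '", x$name, "': ", length(x$entries), " entries, ",
      length(x$normalized), " unique normalized>\n", sep = "")
  invisible(x)
}

#' Load a keyword file
#'
#' One keyword per line; blank lines and `#` comment lines are ignored;
#' surrounding whitespace is stripped; order is preserved.
#'
#' @param path Path to a newline-delimited UTF-8 text file.
#' @param name Label for the list; defaults to the file name.
#' @return A [keyword_list()].
#' @export
load_keyword_file <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("keyword file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  keyword_list(lines, name = name)
}

#' Write a keyword list to a file
#'
#' @param keywords A [keyword_list()] or character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keyword_file <- function(keywords, path) {
  entries <- if (inherits(keywords, "keyword_list")) keywords$entries
             else as.character(keywords)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(entries), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Load the packaged RAS-superfamily gene-symbol catalog
#'
#' The default keyword catalog: a transcription of a curated list of
#' RAS-superfamily gene symbols and their synonyms (273 entries spanning
#' the RAS, RHO, RAB, RAN, ARF and related families; one symbol, ARHH, is
#' duplicated in the source table and is collapsed in the normalized view).
#' The catalog is immutable at runtime: loading twice yields identical
#' lists.
#'
#' @return A [keyword_list()] named `"ras_superfamily"`.
#' @examples
#' cat <- load_ras_superfamily_catalog()
#' "HRAS" %in% cat$entries
#' @export
load_ras_superfamily_catalog <- function() {
  path <- system.file("extdata", "ras_superfamily_catalog.txt",
                      package = "modscanr", mustWork = TRUE)
  load_keyword_file(path, name = "ras_superfamily")
}

#' Load the packaged decoy gene-symbol pool
#'
#' Common human gene symbols outside the RAS superfamily, used by the
#' synthetic-data generator for decoy records. Disjoint (after
#' normalization) from [load_ras_superfamily_catalog()]; the near-miss
#' symbol `HRASLS` (a superstring of `HRAS`) is included deliberately to
#' exercise exact- vs substring-matching behaviour.
#'
#' @return A [keyword_list()] named `"decoy_pool"`.
#' @export
load_decoy_gene_pool <- function() {
  path <- system.file("extdata", "decoy_gene_pool.txt",
                      package = "modscanr", mustWork = TRUE)
  load_keyword_file(path, name = "decoy_pool")
}
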