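# The core database scan: keyword matching over modification records plus
# modification-class / residue / organism filters, and hit summaries.

#' Build a scan query
#'
#' A query pairs a keyword list with the record field it is matched
#' against, a match mode and optional filters. A record matches iff its
#' selected field satisfies the match mode against at least one keyword
#' AND it passes every supplied filter.
#'
#' The default mode, `exact_ci`, is case-insensitive equality on the gene
#' symbol: a gene-list scan should not pick up accidental superstring hits
#' (e.g. `HRASLS` when scanning for `HRAS`). `substring_ci` and `regex`
#' modes support motif-style keywords.
#'
#' @param keywords A [keyword_list()] or character vector. May be empty
#'   only when `allow_filters_only = TRUE`, in which case the keyword
#'   clause passes every record and the filters alone select.
#' @param field Record field to match: `"gene_symbol"` (default),
#'   `"accession"` or `"protein_name"`.
#' @param match_mode `"exact_ci"`, `"substring_ci"` or `"regex"`.
#' @param mod_classes Optional character vector of modification-class
#'   tokens to keep (e.g. `c("m1","m2","m3")`).
#' @param residues Optional character vector of residue letters to keep
#'   (e.g. `"K"`).
#' @param organisms Optional character vector of organism names to keep
#'   (case-insensitive).
#' @param allow_filters_only Allow an empty keyword list, selecting on
#'   filters alone.
#' @return An object of class `keyword_query`.
#' @export
keyword_query <- function(keywords,
                          field = c("gene_symbol", "accession", "protein_name"),
                          match_mode = c("exact_ci", "substring_ci", "regex"),
                          mod_classes = NULL,
                          residues = NULL,
                          organisms = NULL,
                          allow_filters_only = FALSE) {
  field <- match.arg(field)
  match_mode <- match.arg(match_mode)
  if (!inherits(keywords, "keyword_list")) keywords <- keyword_list(keywords)
  if (match_mode == "regex") {
    for (p in keywords$entries) {
      ok <- tryCatch({ grepl(p, ""); TRUE },
                     error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) stop("invalid regular expression: '", p, "'", call. = FALSE)
    }
  }
  if (!is.null(residues)) residues <- toupper(residues)
  structure(
    list(keywords = keywords, field = field, match_mode = match_mode,
         mod_classes = mod_classes, residues = residues,
         organisms = organisms, allow_filters_only = isTRUE(allow_filters_only)),
    class = "keyword_query"
  )
}

# Logical mask of records matching the query; order of `records` preserved.
.scan_mask <- function(records, query) {
  n <- nrow(records)
  if (n == 0L) return(logical(0))
  values <- records[[query$field]]
  kw <- query$keywords$entries
  if (length(kw) == 0L) {
    mask <- rep(query$allow_filters_only, n)
  } else {
    mask <- switch(query$match_mode,
      exact_ci = toupper(values) %in% toupper(kw),
      substring_ci = {
        up <- toupper(values)
        m <- rep(FALSE, n)
        for (k in toupper(kw)) m <- m | grepl(k, up, fixed = TRUE)
        m
      },
      regex = {
        m <- rep(FALSE, n)
        for (k in kw) m <- m | grepl(k, values)
        m
      }
    )
  }
  if (!is.null(query$mod_classes)) {
    mask <- mask & records$mod_class %in% query$mod_classes
  }
  if (!is.null(query$residues)) {
    mask <- mask & records$residue %in% query$residues
  }
  if (!is.null(query$organisms)) {
    mask <- mask & toupper(records$organism) %in% toupper(query$organisms)
  }
  mask
}

#' Scan modification records
#'
#' Applies a [keyword_query()] to parsed modification records. The matched
#' set preserves input row order and the operation is deterministic.
#'
#' @param records Record data frame (see [read_site_dataset()]).
#' @param query A [keyword_query()].
#' @return An object of class `scan_result`: list with `matched` (subset
#'   of `records`, input order) and `summary` (see [summarize_scan()]).
#' @examples
#' recs <- data.frame(
#'   gene_symbol = c("HRAS", "HRASLS"), accession = c("P01112", "Q9GZT9"),
#'   organism = "human", residue = "K", position = c(5L, 10L),
#'   mod_class = "m2", flank_window = "", protein_name = "",
#'   source_row = 1:2
#' )
#' scan_records(recs, keyword_query("HRAS"))$summary$total_matched
#' @export
scan_records <- function(records, query) {
  stopifnot(inherits(query, "keyword_query"))
  mask <- .scan_mask(records, query)
  matched <- records[mask, , drop = FALSE]
  rownames(matched) <- NULL
  structure(
    list(matched = matched,
         summary = summarize_scan(matched, total_scanned = nrow(records))),
    class = "scan_result"
  )
}

#' Summarize matched modification records
#'
#' Sites are deduplicated by the key (accession, position, mod_class):
#' public datasets can repeat one site across rows, and site counts should
#' count sites, not rows. Each deduplicated site is attributed to the
#' (normalized) gene symbol of its first matched row, so the per-gene
#' counts always sum to `distinct_sites`.
#'
#' @param matched Matched record data frame (a subset of the scanned
#'   records).
#' @param total_scanned Total number of records scanned.
#' @return A list of class `scan_summary` with `total_scanned`,
#'   `total_matched`, `distinct_sites`, `distinct_genes`, and named count
#'   vectors `per_gene`, `per_class`, `per_residue` (all over
#'   deduplicated sites).
#' @export
summarize_scan <- function(matched, total_scanned) {
  stopifnot(nrow(matched) <= total_scanned)
  if (nrow(matched) == 0L) {
    return(structure(
      list(total_scanned = total_scanned, total_matched = 0L,
           distinct_sites = 0L, distinct_genes = 0L,
           per_gene = integer(0), per_class = integer(0),
           per_residue = integer(0)),
      class = "scan_summary"
    ))
  }
  key <- paste(matched$accession, matched$position, matched$mod_class,
               sep = "\r")
  first <- !duplicated(key)
  sites <- matched[first, , drop = FALSE]
  count_by <- function(x) {
    t <- table(x)
    stats::setNames(as.integer(t), names(t))
  }
  per_gene <- count_by(toupper(sites$gene_symbol))
  structure(
    list(
      total_scanned = total_scanned,
      total_matched = nrow(matched),
      distinct_sites = nrow(sites),
      distinct_genes = length(per_gene),
      per_gene = per_gene,
      per_class = count_by(sites$mod_class),
      per_residue = count_by(sites$residue)
    ),
    class = "scan_summary"
  )
}

#' @export
print.scan_summary <- function(x, ...) {
  cat("Scan summary: ", x$total_matched, "/", x$total_scanned,
      " records matched; ", x$distinct_sites, " distinct sites in ",
      x$distinct_genes, " genes\n", sep = "")
  invisible(x)
}

#' @export
print.scan_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Write a scan report
#'
#' Writes the matched records as a dialect TSV plus a machine-readable
#' JSON summary. Output is byte-stable given identical input.
#'
#' @param result A [scan_records()] result.
#' @param dir Output directory (created if needed).
#' @param name Stem for the output file names.
#' @param dialect Dialect for the matched-record TSV.
#' @param config Optional named list echoed into the JSON summary (the CLI
#'   passes its effective configuration).
#' @return Named character vector of paths written (`matched`, `summary`).
#' @export
write_scan_report <- function(result, dir, name = "scan",
                              dialect = dsv_dialect(), config = NULL) {
  stopifnot(inherits(result, "scan_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  matched_path <- file.path(dir, paste0(name, "_matched.tsv"))
  summary_path <- file.path(dir, paste0(name, "_summary.json"))
  write_records(result$matched, matched_path, dialect)
  s <- result$summary
  doc <- list(
    version = as.character(utils::packageVersion("modscanr")),
    total_scanned = s$total_scanned,
    total_matched = s$total_matched,
    distinct_sites = s$distinct_sites,
    distinct_genes = s$distinct_genes,
    per_gene = as.list(s$per_gene),
    per_class = as.list(s$per_class),
    per_residue = as.list(s$per_residue)
  )
  if (!is.null(config)) doc$config <- config
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  con <- file(summary_path, open = "wb")
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  close(con)
  c(matched = matched_path, summary = summary_path)
}
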