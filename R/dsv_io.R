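# Reading and writing modification-site datasets in the
# PhosphoSitePlus-style delimiter-separated-value dialect.

#' Describe a modification-site DSV dialect
#'
#' A dialect says how to locate the header of a modification-site table and
#' which column holds each semantic field. The defaults target the public
#' PhosphoSitePlus dataset layout: tab-delimited, a short free-text banner
#' before the header, and columns `GENE`, `ACC_ID`, `MOD_RSD`, `ORGANISM`,
#' `SITE_+/-7_AA`, `PROTEIN`.
#'
#' @param delimiter Field delimiter, exactly one character. Tab by default.
#' @param preamble Either a non-negative integer number of lines to skip
#'   before the header, or `"auto"`: skip lines until one is found that
#'   contains all required column headers.
#' @param column_map Named character vector mapping semantic field names to
#'   column header text. Must cover the required fields `gene`, `accession`
#'   and `mod_code`; `organism`, `flank_window` and `protein_name` are
#'   optional.
#' @return An object of class `dsv_dialect`.
#' @examples
#' dsv_dialect()
#' dsv_dialect(delimiter = ",", preamble = 0)
#' @export
dsv_dialect <- function(delimiter = "\t",
                        preamble = "auto",
                        column_map = c(
                          gene = "GENE",
                          accession = "ACC_ID",
                          mod_code = "MOD_RSD",
                          organism = "ORGANISM",
                          flank_window = "SITE_+/-7_AA",
                          protein_name = "PROTEIN"
                        )) {
  if (!is.character(delimiter) || length(delimiter) != 1L ||
      nchar(delimiter) != 1L) {
    stop("`delimiter` must be exactly one character", call. = FALSE)
  }
  if (!(identical(preamble, "auto") ||
        (is.numeric(preamble) && length(preamble) == 1L && preamble >= 0))) {
    stop("`preamble` must be \"auto\" or a non-negative line count",
         call. = FALSE)
  }
  required <- c("gene", "accession", "mod_code")
  missing <- setdiff(required, names(column_map))
  if (length(missing)) {
    stop("`column_map` is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(delimiter = delimiter, preamble = preamble,
         column_map = column_map),
    class = "dsv_dialect"
  )
}

#' Parse a modification code
#'
#' Modification codes follow the grammar
#' `<residue letter><1-based position>-<class token>`, e.g. `"K5-m2"` for
#' dimethylation of lysine 5. Known class tokens are `p`, `ub`, `ac`, `m1`,
#' `m2`, `m3`, `sm`, `ga`, `gl`; any other token is preserved as
#' `other:<token>` rather than rejected, so scanning does not depend on a
#' closed vocabulary.
#'
#' This is a total function: arbitrary text yields a typed failure
#' (`ok = FALSE` plus a reason), never an error.
#'
#' @param code Character scalar.
#' @return A list with elements `ok` (logical), and on success `residue`
#'   (one uppercase letter), `position` (integer >= 1) and `mod_class`;
#'   on failure `reason`.
#' @examples
#' parse_mod_code("K147-m1")
#' parse_mod_code("X0-zz")$ok
#' @export
parse_mod_code <- function(code) {
  fail <- function(reason) list(ok = FALSE, reason = reason)
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    return(fail("code must be a single character string"))
  }
  code <- trimws(code)
  if (!nzchar(code)) return(fail("empty modification code"))
  m <- regmatches(code, regexec("^([A-Za-z])([0-9]+)-([A-Za-z0-9_]+)$", code))[[1]]
  if (length(m) != 4L) return(fail(paste0("malformed code: '", code, "'")))
  residue <- toupper(m[2])
  position <- suppressWarnings(as.integer(m[3]))
  token <- m[4]
  problems <- character(0)
  if (!(residue %in% AA_LETTERS)) {
    problems <- c(problems, paste0("unknown residue letter '", m[2], "'"))
  }
  if (is.na(position) || position < 1L) {
    problems <- c(problems, "position must be >= 1")
  }
  if (length(problems)) return(fail(paste(problems, collapse = "; ")))
  mod_class <- if (token %in% .KNOWN_MOD_CLASSES) token else paste0("other:", token)
  list(ok = TRUE, residue = residue, position = position, mod_class = mod_class)
}

# Inverse of parse_mod_code for writing.
.format_mod_code <- function(residue, position, mod_class) {
  token <- sub("^other:", "", mod_class)
  paste0(residue, position, "-", token)
}

.empty_records <- function() {
  data.frame(
    gene_symbol = character(0), accession = character(0),
    organism = character(0), residue = character(0),
    position = integer(0), mod_class = character(0),
    flank_window = character(0), protein_name = character(0),
    source_row = integer(0), stringsAsFactors = FALSE
  )
}

.open_text_source <- function(source) {
  if (inherits(source, "connection")) return(list(con = source, close = FALSE))
  if (!file.exists(source)) {
    stop("cannot read source: no such file '", source, "'", call. = FALSE)
  }
  # gzfile() reads both gzip-compressed and plain text transparently.
  con <- tryCatch(gzfile(source, open = "rt", encoding = "UTF-8"),
                  error = function(e) {
                    stop("cannot read source: ", conditionMessage(e),
                         call. = FALSE)
                  })
  list(con = con, close = TRUE)
}

#' Read a modification-site dataset
#'
#' Reads a PhosphoSitePlus-style DSV table into a record data frame. Every
#' body row whose required fields parse yields one record; malformed rows
#' are reported with their line number and a reason, never silently
#' dropped. Gzip-compressed input is accepted transparently.
#'
#' @param source File path (optionally `.gz`) or a readable connection.
#' @param dialect A [dsv_dialect()].
#' @return A list of class `site_dataset` with elements:
#'   * `records`: data frame with columns `gene_symbol`, `accession`,
#'     `organism`, `residue`, `position`, `mod_class`, `flank_window`,
#'     `protein_name`, `source_row` (1-based line number in the file);
#'   * `report`: list with `row_count_total`, `row_count_parsed` and a
#'     `rejected` data frame of (`line`, `reason`).
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' writeLines(c("banner", "GENE\tACC_ID\tMOD_RSD",
#'              "HRAS\tP01112\tK5-m2"), path)
#' read_site_dataset(path)$records
#' @export
read_site_dataset <- function(source, dialect = dsv_dialect()) {
  src <- .open_text_source(source)
  lines <- tryCatch(readLines(src$con, warn = FALSE, encoding = "UTF-8"),
                    error = function(e) {
                      stop("cannot read source: ", conditionMessage(e),
                           call. = FALSE)
                    })
  if (src$close) close(src$con)

  cmap <- dialect$column_map
  required <- c("gene", "accession", "mod_code")
  split_line <- function(x) strsplit(x, dialect$delimiter, fixed = TRUE)[[1]]

  # Locate the header line.
  if (identical(dialect$preamble, "auto")) {
    header_idx <- NA_integer_
    for (i in seq_along(lines)) {
      f <- split_line(lines[i])
      if (all(cmap[required] %in% f)) { header_idx <- i; break }
    }
    if (is.na(header_idx)) {
      stop("no header line containing the required columns (",
           paste(cmap[required], collapse = ", "), ") was found",
           call. = FALSE)
    }
  } else {
    header_idx <- as.integer(dialect$preamble) + 1L
    if (header_idx > length(lines)) {
      stop("preamble skip runs past end of file", call. = FALSE)
    }
  }
  header <- split_line(lines[header_idx])
  for (field in required) {
    if (!(cmap[[field]] %in% header)) {
      stop("required column '", cmap[[field]], "' (field '", field,
           "') not found in header", call. = FALSE)
    }
  }
  col_idx <- vapply(names(cmap), function(f) {
    i <- match(cmap[[f]], header)
    if (is.na(i)) 0L else i
  }, integer(1))

  body_lines <- if (header_idx < length(lines)) {
    seq(header_idx + 1L, length(lines))
  } else integer(0)
  body_lines <- body_lines[nzchar(trimws(lines[body_lines]))]

  n <- length(body_lines)
  fields_list <- strsplit(lines[body_lines], dialect$delimiter, fixed = TRUE)
  get_col <- function(f) {
    i <- col_idx[[f]]
    if (i == 0L) return(rep("", n))
    vapply(fields_list, function(x) {
      if (i > length(x)) "" else trimws(x[i])
    }, character(1))
  }
  gene <- get_col("gene")
  acc <- get_col("accession")
  code <- get_col("mod_code")
  flank <- get_col("flank_window")

  reason <- rep(NA_character_, n)
  reason[!nzchar(gene) | !nzchar(acc) | !nzchar(code)] <-
    "missing required field"
  parsed <- lapply(code, parse_mod_code)
  code_ok <- vapply(parsed, `[[`, logical(1), "ok")
  bad_code <- is.na(reason) & !code_ok
  reason[bad_code] <- vapply(parsed[bad_code], `[[`, character(1), "reason")
  residue <- ifelse(code_ok,
                    vapply(parsed, function(p) if (p$ok) p$residue else "",
                           character(1)), "")
  has_flank <- nzchar(flank)
  bad_len <- is.na(reason) & has_flank & nchar(flank) != 15L
  reason[bad_len] <- "flank window is not 15 characters"
  bad_center <- is.na(reason) & has_flank &
    toupper(substr(flank, 8L, 8L)) != residue
  reason[bad_center] <- "flank window center does not match modified residue"

  keep <- is.na(reason)
  records <- data.frame(
    gene_symbol = gene[keep],
    accession = acc[keep],
    organism = get_col("organism")[keep],
    residue = residue[keep],
    position = vapply(parsed[keep], `[[`, integer(1), "position"),
    mod_class = vapply(parsed[keep], `[[`, character(1), "mod_class"),
    flank_window = flank[keep],
    protein_name = get_col("protein_name")[keep],
    source_row = body_lines[keep],
    stringsAsFactors = FALSE
  )
  if (!nrow(records)) records <- .empty_records()
  rownames(records) <- NULL
  rej_line <- body_lines[!keep]
  rej_reason <- reason[!keep]
  structure(
    list(
      records = records,
      report = list(
        row_count_total = n,
        row_count_parsed = nrow(records),
        rejected = data.frame(line = rej_line, reason = rej_reason,
                              stringsAsFactors = FALSE)
      )
    ),
    class = "site_dataset"
  )
}

#' Write modification records in the DSV dialect
#'
#' Inverse of [read_site_dataset()]: emits a header (all mapped columns, in
#' dialect order) and one row per record, reconstructing the modification
#' code from residue/position/class. Writing then reading reproduces the
#' records field-for-field.
#'
#' @param records Record data frame as returned in
#'   `read_site_dataset()$records` (the `source_row` column is optional).
#' @param sink Output file path or writable connection.
#' @param dialect A [dsv_dialect()].
#' @return Number of rows written, invisibly.
#' @export
write_records <- function(records, sink, dialect = dsv_dialect()) {
  cmap <- dialect$column_map
  field_of <- c(
    gene = "gene_symbol", accession = "accession", mod_code = "mod_code",
    organism = "organism", flank_window = "flank_window",
    protein_name = "protein_name"
  )
  codes <- if (nrow(records)) {
    .format_mod_code(records$residue, records$position, records$mod_class)
  } else character(0)
  tab <- data.frame(row.names = seq_len(nrow(records)))
  for (f in names(cmap)) {
    col <- field_of[[f]]
    tab[[cmap[[f]]]] <- if (identical(col, "mod_code")) {
      codes
    } else if (col %in% names(records)) {
      records[[col]]
    } else {
      rep("", nrow(records))
    }
  }
  lines <- c(
    paste(names(tab), collapse = dialect$delimiter),
    if (nrow(tab)) do.call(paste, c(unname(as.list(tab)),
                                    sep = dialect$delimiter))
  )
  if (inherits(sink, "connection")) {
    writeLines(enc2utf8(lines), sink, useBytes = TRUE)
  } else {
    con <- file(sink, open = "wb")
    on.exit(close(con))
    writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  }
  invisible(nrow(records))
}
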