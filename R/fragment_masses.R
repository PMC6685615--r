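# Theoretical masses and b/y fragment-ion series for modified peptides,
# site-determining ions, and ppm-tolerance peak matching. All masses are
# monoisotopic.

#' Define a modification
#'
#' A modification is defined either by its elemental composition (the
#' monoisotopic delta is then the sum of atomic masses) or by an explicit
#' mass shift. When both are given they must agree to 1e-5 Da.
#'
#' @param name Modification name (used in the bracketed peptide syntax).
#' @param elements Named integer vector of atomic counts, e.g.
#'   `c(C = 1, H = 2)` for a methyl (net CH2). May be `NULL`.
#' @param delta_Da Explicit monoisotopic mass shift; required when
#'   `elements` is `NULL`.
#' @return An object of class `mod_spec` with fields `name`, `elements`,
#'   `delta_Da`.
#' @examples
#' mod_spec("methyl", c(C = 1, H = 2))
#' @export
mod_spec <- function(name, elements = NULL, delta_Da = NULL) {
  if (is.null(elements) && is.null(delta_Da)) {
    stop("supply `elements` and/or `delta_Da`", call. = FALSE)
  }
  if (!is.null(elements)) {
    computed <- .element_mass(elements)
    if (!is.null(delta_Da) && abs(computed - delta_Da) > 1e-5) {
      stop("explicit delta_Da (", delta_Da,
           ") disagrees with elemental composition (", computed, ")",
           call. = FALSE)
    }
    delta_Da <- computed
  }
  structure(list(name = name, elements = elements, delta_Da = delta_Da),
            class = "mod_spec")
}

#' Built-in modification dictionaries
#'
#' Two dictionaries are provided:
#' * `"chemical"` (default): deltas derived from elemental composition —
#'   methyl = CH2, dimethyl = C2H4, trimethyl = C3H6, acetyl = C2H2O.
#' * `"paper-parameter"`: the three methylation deltas exactly as commonly
#'   printed in search-engine parameter listings (+14.0156, +28.0106,
#'   +42.0106). Note these are internally inconsistent with methyl
#'   chemistry — +28.0106 is not 2xCH2 (28.03130) and +42.0106 equals the
#'   acetyl delta, not 3xCH2 (42.04695). The dictionary records them
#'   verbatim for reproducibility without endorsing an interpretation.
#'
#' @param mode `"chemical"` or `"paper-parameter"`.
#' @return Named list of [mod_spec()] objects.
#' @export
builtin_mods <- function(mode = c("chemical", "paper-parameter")) {
  mode <- match.arg(mode)
  if (mode == "chemical") {
    list(
      methyl = mod_spec("methyl", c(C = 1, H = 2)),
      dimethyl = mod_spec("dimethyl", c(C = 2, H = 4)),
      trimethyl = mod_spec("trimethyl", c(C = 3, H = 6)),
      acetyl = mod_spec("acetyl", c(C = 2, H = 2, O = 1))
    )
  } else {
    list(
      methyl = mod_spec("methyl", delta_Da = 14.0156),
      dimethyl = mod_spec("dimethyl", delta_Da = 28.0106),
      trimethyl = mod_spec("trimethyl", delta_Da = 42.0106)
    )
  }
}

#' Monoisotopic mass shift of a modification
#'
#' @param spec A [mod_spec()].
#' @param decimals Optional number of decimal places to round to
#'   (standard half-even rounding); `NULL` returns full precision.
#' @return Mass shift in Da.
#' @examples
#' modification_delta(builtin_mods()$methyl, decimals = 5)
#' @export
modification_delta <- function(spec, decimals = NULL) {
  stopifnot(inherits(spec, "mod_spec"))
  d <- spec$delta_Da
  if (is.null(decimals)) d else round(d, decimals)
}

#' Construct a modified peptide
#'
#' @param sequence Uppercase amino-acid string.
#' @param mods List of modifications, each a list with `position` (1-based,
#'   within the sequence, at most one per position) and `spec` (a
#'   [mod_spec()]). Empty list for an unmodified peptide.
#' @param charge Positive precursor charge (used by m/z helpers).
#' @return An object of class `modified_peptide`.
#' @export
modified_peptide <- function(sequence, mods = list(), charge = 1L) {
  .check_protein_seq(sequence, "sequence")
  n <- nchar(sequence)
  pos <- vapply(mods, function(m) as.integer(m$position), integer(1))
  if (length(pos)) {
    if (any(pos < 1L | pos > n)) {
      stop("modification position outside the sequence", call. = FALSE)
    }
    if (anyDuplicated(pos)) {
      stop("at most one modification per position", call. = FALSE)
    }
    for (m in mods) stopifnot(inherits(m$spec, "mod_spec"))
  }
  if (charge < 1) stop("charge must be positive", call. = FALSE)
  structure(list(sequence = sequence, mods = mods, charge = as.integer(charge)),
            class = "modified_peptide")
}

#' Parse the bracketed peptide syntax
#'
#' Residue letters with bracketed modification names, one modification per
#' bracket, attached to the preceding residue:
#' `MTEYK[dimethyl]LVVVGAGGVGK`.
#'
#' @param text Peptide string.
#' @param mods_table Named list of [mod_spec()]s resolving bracket names
#'   (default [builtin_mods()]).
#' @param charge Precursor charge.
#' @return A [modified_peptide()].
#' @export
parse_peptide_string <- function(text, mods_table = builtin_mods(),
                                 charge = 1L) {
  chars <- strsplit(text, "")[[1]]
  seq_chars <- character(0)
  mods <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) {
        stop("unterminated '[' at offset ", i, call. = FALSE)
      }
      name <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (length(seq_chars) == 0L) {
        stop("modification bracket at offset ", i,
             " has no preceding residue", call. = FALSE)
      }
      if (!(name %in% names(mods_table))) {
        stop("unknown modification '", name, "' at offset ", i, call. = FALSE)
      }
      pos <- length(seq_chars)
      if (any(vapply(mods, function(m) m$position == pos, logical(1)))) {
        stop("second modification bracket for residue at position ", pos,
             " (offset ", i, ")", call. = FALSE)
      }
      mods <- c(mods, list(list(position = pos, spec = mods_table[[name]])))
      i <- j + 1L
    } else if (toupper(ch) %in% AA_LETTERS) {
      seq_chars <- c(seq_chars, toupper(ch))
      i <- i + 1L
    } else {
      stop("illegal character '", ch, "' at offset ", i, call. = FALSE)
    }
  }
  modified_peptide(paste(seq_chars, collapse = ""), mods, charge)
}

.mod_positions <- function(pep) {
  vapply(pep$mods, function(m) m$position, integer(1))
}

.mod_deltas <- function(pep) {
  vapply(pep$mods, function(m) m$spec$delta_Da, numeric(1))
}

#' Neutral monoisotopic mass of a modified peptide
#'
#' Sum of residue masses, plus water, plus all modification deltas.
#'
#' @param pep A [modified_peptide()].
#' @return Mass in Da.
#' @examples
#' peptide_neutral_mass(modified_peptide("G"))  # 75.03203
#' @export
peptide_neutral_mass <- function(pep) {
  stopifnot(inherits(pep, "modified_peptide"))
  res <- strsplit(pep$sequence, "")[[1]]
  sum(RESIDUE_MASS[res]) + WATER_MASS + sum(.mod_deltas(pep))
}

#' Theoretical b/y fragment-ion series
#'
#' For a peptide of length n there are n-1 ions per series per charge. A
#' `b_i` ion covers N-terminal positions `1..i`; a `y_j` ion covers
#' C-terminal positions `(n-j+1)..n` and carries a water. m/z is
#' `(neutral + z * proton) / z` with the proton at 1.007276 Da.
#'
#' @param pep A [modified_peptide()].
#' @param series Subset of `c("b", "y")`.
#' @param max_charge Ions are generated for all charges `1..max_charge`.
#' @return Data frame with columns `series`, `index`, `charge`, `mz`,
#'   `carries_mods` (comma-joined modified positions covered by the ion,
#'   `""` if none).
#' @export
fragment_series <- function(pep, series = c("b", "y"), max_charge = 1L) {
  stopifnot(inherits(pep, "modified_peptide"))
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  n <- nchar(pep$sequence)
  if (n < 2L) stop("fragment series require a peptide of length >= 2",
                   call. = FALSE)
  res <- strsplit(pep$sequence, "")[[1]]
  masses <- RESIDUE_MASS[res]
  mpos <- .mod_positions(pep)
  mdel <- .mod_deltas(pep)
  prefix <- cumsum(masses)  # prefix[i] = sum residues 1..i
  mod_prefix <- vapply(seq_len(n), function(i) sum(mdel[mpos <= i]),
                       numeric(1))
  rows <- list()
  for (s in series) {
    for (i in seq_len(n - 1L)) {
      if (s == "b") {
        neutral <- prefix[i] + mod_prefix[i]
        covered <- mpos[mpos <= i]
      } else {
        start <- n - i + 1L
        neutral <- (prefix[n] - prefix[start - 1L]) + WATER_MASS +
          (mod_prefix[n] - mod_prefix[start - 1L])
        covered <- mpos[mpos >= start]
      }
      for (z in seq_len(max_charge)) {
        rows[[length(rows) + 1L]] <- data.frame(
          series = s, index = i, charge = z,
          mz = (neutral + z * PROTON_MASS) / z,
          carries_mods = paste(sort(covered), collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Site-determining ions for an alternative modification placement
#'
#' Given a peptide carrying exactly one variable modification, returns the
#' theoretical ions whose m/z differs between the assigned placement and an
#' alternative placement — the ions that discriminate the two site
#' assignments (equivalently, ions covering one candidate position but not
#' the other). Manual validation of a methylated peptide amounts to
#' checking these ions in the observed spectrum.
#'
#' @param pep A [modified_peptide()] with exactly one modification.
#' @param alt_position Alternative 1-based position for that modification.
#' @param max_charge Charges to consider.
#' @return Data frame of ions (as in [fragment_series()]) from the
#'   assigned placement; empty when `alt_position` equals the assigned
#'   position.
#' @export
site_determining_ions <- function(pep, alt_position, max_charge = 1L) {
  stopifnot(inherits(pep, "modified_peptide"))
  if (length(pep$mods) != 1L) {
    stop("site-determining ions are defined for exactly one variable ",
         "modification (peptide has ", length(pep$mods), ")", call. = FALSE)
  }
  n <- nchar(pep$sequence)
  if (alt_position < 1L || alt_position > n) {
    stop("alt_position outside the sequence", call. = FALSE)
  }
  assigned <- fragment_series(pep, max_charge = max_charge)
  alt_pep <- modified_peptide(
    pep$sequence,
    list(list(position = alt_position, spec = pep$mods[[1]]$spec)),
    pep$charge
  )
  alt <- fragment_series(alt_pep, max_charge = max_charge)
  differs <- abs(assigned$mz - alt$mz) > 1e-9
  out <- assigned[differs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match theoretical ions against observed peaks
#'
#' Greedy nearest matching in relative (ppm) error: all (ion, peak) pairs
#' within tolerance are ranked by absolute ppm error and assigned
#' greedily, each theoretical ion and each observed peak used at most
#' once. The result is invariant to the order of the observed peaks.
#'
#' @param theoretical Ion data frame from [fragment_series()].
#' @param observed Peak list: data frame with columns `mz` (positive) and
#'   `intensity` (>= 0).
#' @param tolerance_ppm Match tolerance in parts per million (> 0).
#' @return List with `matched` (ion rows plus `obs_mz`, `intensity`,
#'   `ppm_error`), `unmatched_ions` (ion rows), and `coverage`
#'   (matched ions / theoretical ions).
#' @export
match_peaks <- function(theoretical, observed, tolerance_ppm = 10) {
  stopifnot(tolerance_ppm > 0)
  if (nrow(observed)) {
    stopifnot(all(observed$mz > 0), all(observed$intensity >= 0))
  }
  n_t <- nrow(theoretical)
  if (n_t == 0L) {
    return(list(matched = cbind(theoretical,
                                obs_mz = numeric(0), intensity = numeric(0),
                                ppm_error = numeric(0)),
                unmatched_ions = theoretical, coverage = NaN))
  }
  pairs <- NULL
  if (nrow(observed)) {
    grid <- expand.grid(ion = seq_len(n_t), peak = seq_len(nrow(observed)))
    ppm <- (observed$mz[grid$peak] - theoretical$mz[grid$ion]) /
      theoretical$mz[grid$ion] * 1e6
    keep <- abs(ppm) <= tolerance_ppm
    pairs <- data.frame(ion = grid$ion[keep], peak = grid$peak[keep],
                        ppm = ppm[keep])
    # rank by |ppm|, then by theoretical m/z and observed m/z for a
    # deterministic, observed-order-invariant tie-break
    pairs <- pairs[order(abs(pairs$ppm), theoretical$mz[pairs$ion],
                         observed$mz[pairs$peak]), , drop = FALSE]
  }
  ion_used <- rep(FALSE, n_t)
  peak_used <- rep(FALSE, nrow(observed))
  ion_peak <- rep(NA_integer_, n_t)
  ion_ppm <- rep(NA_real_, n_t)
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$ion[k]; p <- pairs$peak[k]
      if (!ion_used[i] && !peak_used[p]) {
        ion_used[i] <- TRUE
        peak_used[p] <- TRUE
        ion_peak[i] <- p
        ion_ppm[i] <- pairs$ppm[k]
      }
    }
  }
  matched <- theoretical[ion_used, , drop = FALSE]
  if (nrow(matched)) {
    mp <- ion_peak[ion_used]
    matched$obs_mz <- observed$mz[mp]
    matched$intensity <- observed$intensity[mp]
    matched$ppm_error <- ion_ppm[ion_used]
  } else {
    matched$obs_mz <- numeric(0)
    matched$intensity <- numeric(0)
    matched$ppm_error <- numeric(0)
  }
  unmatched <- theoretical[!ion_used, , drop = FALSE]
  rownames(matched) <- NULL
  rownames(unmatched) <- NULL
  list(matched = matched, unmatched_ions = unmatched,
       coverage = sum(ion_used) / n_t)
}

#' Read a two-column peak list
#'
#' @param path TSV with columns m/z and intensity (header optional).
#' @return Data frame with columns `mz`, `intensity`.
#' @export
read_peak_list <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- !grepl("^[0-9.eE+-]+\t", first)
  tab <- utils::read.delim(path, header = has_header,
                           col.names = c("mz", "intensity"))
  stopifnot(all(tab$mz > 0))
  tab
}

#' Write a peak list as two-column TSV
#'
#' @param peaks Data frame with columns `mz`, `intensity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  lines <- c("mz\tintensity",
             sprintf("%.6f\t%.6f", peaks$mz, peaks$intensity))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
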