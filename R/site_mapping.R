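# Residue-position equivalence between small-GTPase homologs and a
# reference (HRAS numbering), via global pairwise alignment. Each homolog
# is aligned pairwise to the reference (star topology): equivalence labels
# only need homolog<->reference maps, and pairwise alignments keep the
# brute-force test oracle tractable.

#' Alignment scoring scheme
#'
#' Global alignment uses an affine gap model: a gap run of length L costs
#' `gap_open + L * gap_extend`. Terminal gaps are penalized like internal
#' gaps (true global alignment).
#'
#' @param matrix Substitution matrix name (a matrix shipped with
#'   Biostrings; `"BLOSUM62"` default).
#' @param gap_open Non-negative gap opening penalty (default 10).
#' @param gap_extend Non-negative per-position gap extension penalty
#'   (default 1); must not exceed `gap_open`.
#' @return An object of class `scoring_scheme` with the resolved
#'   substitution matrix in `$matrix`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  if (gap_open < 0 || gap_extend < 0) {
    stop("gap penalties must be non-negative", call. = FALSE)
  }
  if (gap_extend > gap_open) {
    stop("`gap_extend` must not exceed `gap_open`", call. = FALSE)
  }
  if (is.character(matrix)) {
    name <- matrix
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    matrix <- get(name, envir = env)
  } else {
    name <- "custom"
  }
  sub <- matrix[AA_LETTERS, AA_LETTERS]
  if (!isTRUE(all.equal(sub, t(sub)))) {
    stop("substitution matrix is not symmetric over the 20 amino acids",
         call. = FALSE)
  }
  structure(
    list(matrix_name = name, matrix = matrix,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "scoring_scheme"
  )
}

.check_protein_seq <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop(what, " must be a nonempty character scalar", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!(chars %in% AA_LETTERS))
  if (length(bad)) {
    stop(what, " contains illegal characters at position(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}

#' Global pairwise alignment of a homolog against a reference
#'
#' Needleman-Wunsch global alignment with affine gaps (via Biostrings).
#' Deterministic: repeated calls return the identical alignment.
#'
#' @param ref_seq Reference protein sequence (uppercase, 20 standard
#'   amino-acid letters).
#' @param hom_seq Homolog protein sequence.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `pairwise_alignment`: list with equal-length
#'   gapped strings `ref_aligned` and `hom_aligned`, and `score`.
#' @examples
#' aln <- align_global("MTEYK", "MTEYK")
#' aln$score
#' @export
align_global <- function(ref_seq, hom_seq, scheme = scoring_scheme()) {
  .check_protein_seq(ref_seq, "ref_seq")
  .check_protein_seq(hom_seq, "hom_seq")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(ref_seq),
    subject = Biostrings::AAString(hom_seq),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend,
    type = "global"
  )
  out <- structure(
    list(
      ref_aligned = as.character(Biostrings::alignedPattern(aln)),
      hom_aligned = as.character(Biostrings::alignedSubject(aln)),
      score = Biostrings::score(aln)
    ),
    class = "pairwise_alignment"
  )
  stopifnot(nchar(out$ref_aligned) == nchar(out$hom_aligned))
  out
}

#' Residue-position correspondence from an alignment
#'
#' One (reference position, homolog position) pair per column where both
#' sequences have a residue; columns with a gap on either side contribute
#' no pair. The pairs are strictly increasing in both coordinates and form
#' a bijection between the mapped position subsets.
#'
#' @param alignment A [align_global()] result (or any list with
#'   `ref_aligned` / `hom_aligned`).
#' @return A data frame of class `position_map` with integer columns
#'   `ref_position` and `hom_position` (both 1-based).
#' @export
build_position_map <- function(alignment) {
  ref <- strsplit(alignment$ref_aligned, "")[[1]]
  hom <- strsplit(alignment$hom_aligned, "")[[1]]
  stopifnot(length(ref) == length(hom))
  ref_pos <- cumsum(ref != "-")
  hom_pos <- cumsum(hom != "-")
  both <- ref != "-" & hom != "-"
  out <- data.frame(ref_position = as.integer(ref_pos[both]),
                    hom_position = as.integer(hom_pos[both]))
  class(out) <- c("position_map", "data.frame")
  out
}

#' Reference position equivalent to a homolog position
#'
#' @param map A [build_position_map()] result.
#' @param hom_position Homolog residue position (1-based).
#' @return The paired reference position, or `NA_integer_` when the
#'   homolog position aligns to a reference gap or lies outside the
#'   alignment.
#' @export
equivalent_position <- function(map, hom_position) {
  stopifnot(hom_position >= 1)
  i <- match(hom_position, map$hom_position)
  if (is.na(i)) NA_integer_ else map$ref_position[i]
}

#' Conservation of a residue at a reference position
#'
#' Fraction of homologs carrying `residue_letter` at the position
#' equivalent to `ref_position`. Homologs whose alignment has no residue
#' at that reference column (a deletion) count in the denominator: a
#' deletion is non-conservation.
#'
#' @param maps List of [build_position_map()] results, all built against
#'   the same reference.
#' @param hom_seqs Character vector of the homolog sequences, parallel to
#'   `maps`.
#' @param ref_position Reference position (1-based).
#' @param residue_letter Residue letter whose conservation is assessed.
#' @param ref_length Optional reference length; when supplied,
#'   `ref_position` outside `1..ref_length` is an error.
#' @return Fraction in `[0, 1]`.
#' @export
column_conservation <- function(maps, hom_seqs, ref_position, residue_letter,
                                ref_length = NULL) {
  if (length(maps) == 0L) {
    stop("conservation is undefined for an empty homolog set", call. = FALSE)
  }
  stopifnot(length(maps) == length(hom_seqs))
  if (!is.null(ref_length) &&
      (ref_position < 1 || ref_position > ref_length)) {
    stop("ref_position ", ref_position, " outside reference length ",
         ref_length, call. = FALSE)
  }
  residue_letter <- toupper(residue_letter)
  hits <- vapply(seq_along(maps), function(i) {
    j <- match(ref_position, maps[[i]]$ref_position)
    if (is.na(j)) return(FALSE)
    hp <- maps[[i]]$hom_position[j]
    toupper(substr(hom_seqs[i], hp, hp)) == residue_letter
  }, logical(1))
  sum(hits) / length(maps)
}

#' Annotate records with reference-site equivalence labels
#'
#' For each record, aligns its protein (looked up by accession) to the
#' reference and labels the record with the reference site its position is
#' equivalent to. Records whose accession has no sequence are labeled
#' `"unmapped"`, never dropped; positions equivalent to no reference site
#' (or aligned to a reference gap) are labeled `"none"`.
#'
#' @param records Record data frame (needs `accession` and `position`).
#' @param ref_seq Reference protein sequence.
#' @param ref_sites Data frame with columns `position` and `label`
#'   (reference sites of interest, e.g. K5/K16/K117 in HRAS numbering).
#' @param sequence_lookup Named character vector (or `AAStringSet`)
#'   mapping accession to protein sequence.
#' @param scheme A [scoring_scheme()].
#' @return `records` with added columns `equiv_ref_position` (integer,
#'   `NA` when unmapped/none) and `equiv_label`.
#' @export
annotate_equivalence <- function(records, ref_seq, ref_sites,
                                 sequence_lookup,
                                 scheme = scoring_scheme()) {
  stopifnot(all(c("position", "label") %in% names(ref_sites)))
  if (methods::is(sequence_lookup, "XStringSet")) {
    sequence_lookup <- stats::setNames(as.character(sequence_lookup),
                                       names(sequence_lookup))
  }
  maps <- list()
  n <- nrow(records)
  equiv_pos <- rep(NA_integer_, n)
  label <- rep("none", n)
  for (i in seq_len(n)) {
    acc <- records$accession[i]
    if (!(acc %in% names(sequence_lookup))) {
      label[i] <- "unmapped"
      next
    }
    if (is.null(maps[[acc]])) {
      aln <- align_global(ref_seq, sequence_lookup[[acc]], scheme)
      maps[[acc]] <- build_position_map(aln)
    }
    rp <- equivalent_position(maps[[acc]], records$position[i])
    equiv_pos[i] <- rp
    if (!is.na(rp)) {
      j <- match(rp, ref_sites$position)
      if (!is.na(j)) label[i] <- ref_sites$label[j]
    }
  }
  records$equiv_ref_position <- equiv_pos
  records$equiv_label <- label
  records
}
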