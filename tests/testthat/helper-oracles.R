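# Independent oracles and fixture builders shared across tests.

# Naive scan oracle: reads every row, tests every condition with scalar
# logic. Returns the matched row indices.
naive_scan_idx <- function(records, keywords, field = "gene_symbol",
                           mode = "exact_ci", mod_classes = NULL,
                           residues = NULL, organisms = NULL,
                           allow_filters_only = FALSE) {
  hits <- integer(0)
  for (r in seq_len(nrow(records))) {
    v <- records[[field]][r]
    if (length(keywords) == 0L) {
      km <- allow_filters_only
    } else {
      km <- FALSE
      for (k in keywords) {
        km <- switch(mode,
          exact_ci = tolower(v) == tolower(k),
          substring_ci = grepl(tolower(k), tolower(v), fixed = TRUE),
          regex = grepl(k, v)
        )
        if (km) break
      }
    }
    ok <- km
    if (ok && !is.null(mod_classes)) ok <- records$mod_class[r] %in% mod_classes
    if (ok && !is.null(residues)) ok <- records$residue[r] %in% toupper(residues)
    if (ok && !is.null(organisms)) {
      ok <- tolower(records$organism[r]) %in% tolower(organisms)
    }
    if (ok) hits <- c(hits, r)
  }
  hits
}

# Brute-force global alignment score: enumerate every alignment (move
# sequences over diagonal / gap-in-hom / gap-in-ref), score with affine
# gaps (a run of length L costs open + L * extend), take the maximum.
brute_force_align_score <- function(a, b, sub, open = 10, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i == na && j == nb) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i < na && j < nb) {
      rec(i + 1L, j + 1L, score + sub[A[i + 1L], B[j + 1L]], "D")
    }
    if (i < na) {
      rec(i + 1L, j, score - extend - (if (identical(prev, "U")) 0 else open), "U")
    }
    if (j < nb) {
      rec(i, j + 1L, score - extend - (if (identical(prev, "L")) 0 else open), "L")
    }
  }
  rec(0L, 0L, 0, "")
  best
}

random_protein <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

# Small random record frame for scanner property tests (independent of the
# package's own generator).
random_records <- function(n, genes = c("HRAS", "HRASLS", "KRAS2A", "RAN",
                                        "TP53", "EGFR", "hras", "RAB5B")) {
  data.frame(
    gene_symbol = sample(genes, n, replace = TRUE),
    accession = sprintf("P%05d", sample(1:500, n, replace = TRUE)),
    organism = sample(c("human", "mouse", "rat"), n, replace = TRUE),
    residue = sample(c("K", "R", "S", "T", "Y"), n, replace = TRUE),
    position = sample(1:300, n, replace = TRUE),
    mod_class = sample(c("m1", "m2", "m3", "ac", "ub", "p"), n,
                       replace = TRUE),
    flank_window = "",
    protein_name = "protein",
    source_row = seq_len(n) + 4L,
    stringsAsFactors = FALSE
  )
}

# Ten-record fixture used by the scanner match-mode tests: 3x HRAS,
# 1x HRASLS (superstring near-miss) and 6 decoys.
hras_fixture <- function() {
  data.frame(
    gene_symbol = c("HRAS", "hras", "HRAS", "HRASLS", "TP53", "EGFR",
                    "MYC", "ACTB", "RAN", "GAPDH"),
    accession = sprintf("P%05d", 1:10),
    organism = "human",
    residue = "K",
    position = 1:10 * 3L,
    mod_class = rep(c("m1", "m2"), 5),
    flank_window = "",
    protein_name = "x",
    source_row = 1:10,
    stringsAsFactors = FALSE
  )
}

# Random peptide with 0-2 methyl-class modifications on distinct positions.
random_modified_peptide <- function(len, n_mods = 0) {
  mods_pool <- builtin_mods("chemical")[c("methyl", "dimethyl", "trimethyl")]
  mods <- list()
  if (n_mods > 0) {
    pos <- sample(len, n_mods)
    for (p in pos) {
      mods <- c(mods, list(list(position = p,
                                spec = mods_pool[[sample(3, 1)]])))
    }
  }
  modified_peptide(random_protein(len), mods)
}
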