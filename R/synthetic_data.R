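# Seeded generators for fixture modification-site datasets (with ground
# truth) and synthetic MS2 peak lists. The generators let every other
# module be tested without access to licence-restricted databases.

# One integer seed drives a named PRNG stream per generator, so adding a
# generator never shifts existing fixtures. The stream seed is a simple
# 31-bit hash of (seed, stream name).
.stream_seed <- function(seed, stream) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a pinned, seeded RNG without disturbing the
# caller's RNG state.
.with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(.stream_seed(seed, stream), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Synthesize a ±7-residue flanking window: modified residue at the center,
# random residues elsewhere, '_' padding where the window runs past the
# protein termini.
.make_flank <- function(residue, position, protein_length) {
  idx <- (position - 7L):(position + 7L)
  chars <- ifelse(idx < 1L | idx > protein_length, "_",
                  sample(AA_LETTERS, 15L, replace = TRUE))
  chars[8L] <- residue
  paste(chars, collapse = "")
}

#' Specify a synthetic modification-site dataset
#'
#' @param n_total Total number of body rows.
#' @param planted Data frame of ground-truth rows to plant, with columns
#'   `gene`, `accession`, `residue`, `position`, `mod_class`. Typically
#'   catalog-gene lysine-methylation sites (see [plant_catalog_sites()]).
#' @param decoy_gene_pool [keyword_list()] (or character vector) of decoy
#'   gene symbols; must be disjoint, after normalization, from
#'   `catalog`.
#' @param class_proportions Modification-class mix for decoy rows. The
#'   default emulates a methylation-centric dataset: mostly mono-, di-,
#'   trimethyl rows with minor acetylation/ubiquitylation/phosphorylation
#'   contamination.
#' @param organisms Organism labels sampled for decoy rows (planted rows
#'   are always `"human"`).
#' @param organism_weights Sampling weights for `organisms`.
#' @param seed Integer seed; the generator is deterministic given the
#'   seed.
#' @param catalog Keyword list the decoy pool must avoid (default the
#'   packaged RAS-superfamily catalog).
#' @return An object of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_total,
                                   planted,
                                   decoy_gene_pool = load_decoy_gene_pool(),
                                   class_proportions = c(
                                     m1 = 0.50, m2 = 0.20, m3 = 0.10,
                                     ac = 0.08, ub = 0.07, p = 0.05
                                   ),
                                   organisms = c("human", "mouse", "rat"),
                                   organism_weights = c(0.7, 0.2, 0.1),
                                   seed = 1L,
                                   catalog = load_ras_superfamily_catalog()) {
  if (!inherits(decoy_gene_pool, "keyword_list")) {
    decoy_gene_pool <- keyword_list(decoy_gene_pool, "decoy_pool")
  }
  stopifnot(
    is.data.frame(planted),
    all(c("gene", "accession", "residue", "position", "mod_class")
        %in% names(planted)),
    nrow(planted) <= n_total,
    abs(sum(class_proportions) - 1) <= 1e-9,
    length(organisms) == length(organism_weights)
  )
  overlap <- intersect(decoy_gene_pool$normalized, catalog$normalized)
  if (length(overlap)) {
    stop("decoy gene pool overlaps the catalog: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_total = as.integer(n_total), planted = planted,
         decoy_gene_pool = decoy_gene_pool,
         class_proportions = class_proportions,
         organisms = organisms, organism_weights = organism_weights,
         seed = as.integer(seed)),
    class = "synthetic_dataset_spec"
  )
}

#' Plant catalog-gene lysine-methylation sites
#'
#' Draws `n_genes` distinct symbols from the catalog and distributes
#' `n_sites` distinct lysine mono-/di-/trimethylation sites across them
#' (every gene receives at least one site). Deterministic given the seed.
#'
#' @param n_sites Number of planted sites.
#' @param n_genes Number of distinct catalog genes carrying them
#'   (`n_genes <= n_sites`).
#' @param seed Integer seed.
#' @param catalog Source [keyword_list()].
#' @return Data frame suitable as `planted` in
#'   [synthetic_dataset_spec()].
#' @export
plant_catalog_sites <- function(n_sites, n_genes, seed = 1L,
                                catalog = load_ras_superfamily_catalog()) {
  stopifnot(n_genes <= n_sites, n_genes <= length(catalog$normalized))
  .with_stream(seed, "plant_catalog_sites", {
    genes <- sample(catalog$normalized, n_genes)
    # every gene once, then the remainder at random
    gene_of <- c(genes, sample(genes, n_sites - n_genes, replace = TRUE))
    acc <- paste0("SYN-", gene_of)
    # distinct positions within each accession
    position <- integer(n_sites)
    for (g in unique(acc)) {
      i <- which(acc == g)
      position[i] <- sample(5:300, length(i))
    }
    data.frame(
      gene = gene_of, accession = acc, residue = "K",
      position = position,
      mod_class = sample(c("m1", "m2", "m3"), n_sites, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic modification-site dataset
#'
#' Emits a complete DSV file in the default dialect — a 3-line banner, the
#' header, and `n_total` body rows — with the planted rows interleaved
#' uniformly at random among decoy rows, plus a ground-truth table giving
#' each planted site's emitted line number. Byte-identical output for
#' identical (spec, seed).
#'
#' Decoy rows draw gene symbols from the decoy pool, residues consistent
#' with their modification class (K/R for methyl classes, K for
#' acetyl/ubiquityl, S/T/Y for phospho), and flanking windows consistent
#' with residue and position ('_' padding at termini).
#'
#' @param spec A [synthetic_dataset_spec()].
#' @param path Optional output file path; when `NULL` only the lines are
#'   returned.
#' @return List with `lines` (character vector of file lines),
#'   `ground_truth` (planted table plus `body_row` and `file_line`), and
#'   `path`.
#' @export
generate_site_dataset <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  dialect <- dsv_dialect()
  n <- spec$n_total
  n_plant <- nrow(spec$planted)
  n_decoy <- n - n_plant
  .with_stream(spec$seed, "site_dataset", {
    classes <- names(spec$class_proportions)
    decoy_class <- if (n_decoy) {
      sample(classes, n_decoy, replace = TRUE, prob = spec$class_proportions)
    } else character(0)
    decoy_residue <- vapply(decoy_class, function(cl) {
      switch(cl,
             m1 = , m2 = , m3 = sample(c("K", "R"), 1, prob = c(0.6, 0.4)),
             ac = , ub = "K",
             p = sample(c("S", "T", "Y"), 1, prob = c(0.6, 0.25, 0.15)),
             "K")
    }, character(1))
    decoy_gene <- if (n_decoy) {
      sample(spec$decoy_gene_pool$entries, n_decoy, replace = TRUE)
    } else character(0)
    decoy_pos <- if (n_decoy) sample(1:800, n_decoy, replace = TRUE) else integer(0)
    decoy_len <- decoy_pos + sample(0:400, max(n_decoy, 1), replace = TRUE)[seq_len(n_decoy)]
    decoy <- data.frame(
      gene_symbol = decoy_gene,
      accession = sprintf("Q%05d", sample(10000:99999, n_decoy,
                                          replace = TRUE)),
      organism = if (n_decoy) {
        sample(spec$organisms, n_decoy, replace = TRUE,
               prob = spec$organism_weights)
      } else character(0),
      residue = decoy_residue,
      position = decoy_pos,
      mod_class = decoy_class,
      protein_name = if (n_decoy) paste0(decoy_gene, " protein") else character(0),
      stringsAsFactors = FALSE
    )
    decoy$flank_window <- vapply(seq_len(n_decoy), function(i) {
      .make_flank(decoy$residue[i], decoy$position[i], decoy_len[i])
    }, character(1))

    plant <- data.frame(
      gene_symbol = spec$planted$gene,
      accession = spec$planted$accession,
      organism = "human",
      residue = spec$planted$residue,
      position = spec$planted$position,
      mod_class = spec$planted$mod_class,
      protein_name = paste0(spec$planted$gene, " GTPase"),
      stringsAsFactors = FALSE
    )
    plant$flank_window <- vapply(seq_len(n_plant), function(i) {
      .make_flank(plant$residue[i], plant$position[i],
                  plant$position[i] + 200L)
    }, character(1))

    body_row_of_plant <- sort(sample(n, n_plant))
    is_plant <- logical(n)
    is_plant[body_row_of_plant] <- TRUE
    combined <- rbind(plant, decoy)
    src <- integer(n)
    src[is_plant] <- seq_len(n_plant)
    src[!is_plant] <- n_plant + seq_len(n_decoy)
    combined <- combined[src, , drop = FALSE]
    rownames(combined) <- NULL

    cmap <- dialect$column_map
    codes <- .format_mod_code(combined$residue, combined$position,
                              combined$mod_class)
    cols <- list(
      gene = combined$gene_symbol, accession = combined$accession,
      mod_code = codes, organism = combined$organism,
      flank_window = combined$flank_window,
      protein_name = combined$protein_name
    )
    header <- paste(cmap[names(cols)], collapse = dialect$delimiter)
    body <- do.call(paste, c(unname(cols), sep = dialect$delimiter))
    preamble <- c(
      "synthetic modification-site dataset",
      paste0("generator=modscanr seed=", spec$seed, " n_total=", n),
      ""
    )
    lines <- c(preamble, header, body)

    ground_truth <- spec$planted
    ground_truth$body_row <- body_row_of_plant
    ground_truth$file_line <- body_row_of_plant + length(preamble) + 1L

    if (!is.null(path)) {
      con <- file(path, open = "wb")
      writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
      close(con)
    }
    list(lines = lines, ground_truth = ground_truth, path = path)
  })
}

#' Generate a synthetic MS2 peak list from a peptide's theoretical ions
#'
#' Samples a subset of the theoretical singly-charged b/y ions of size
#' `round(ion_coverage * (2n - 2))`, perturbs each by Gaussian relative
#' (ppm) error, and adds uniformly distributed noise peaks over the
#' observed m/z range. Deterministic given the seed.
#'
#' @param pep A [modified_peptide()].
#' @param ion_coverage Fraction of theoretical ions emitted, in `[0, 1]`.
#' @param n_noise_peaks Number of noise peaks.
#' @param jitter_ppm_sd Standard deviation of the Gaussian ppm error.
#' @param seed Integer seed.
#' @return List with `peaks` (data frame `mz`, `intensity`; emitted ions
#'   first, then noise) and `truth` (data frame mapping each emitted ion —
#'   `series`, `index`, `charge`, `theo_mz` — to its `peak_index` in
#'   `peaks`).
#' @export
generate_peak_list <- function(pep, ion_coverage = 1, n_noise_peaks = 0,
                               jitter_ppm_sd = 0, seed = 1L) {
  stopifnot(ion_coverage >= 0, ion_coverage <= 1, n_noise_peaks >= 0)
  theo <- fragment_series(pep, max_charge = 1L)
  .with_stream(seed, "peak_list", {
    k <- round(ion_coverage * nrow(theo))
    emit <- if (k > 0) sort(sample(nrow(theo), k)) else integer(0)
    ion_mz <- theo$mz[emit] *
      (1 + stats::rnorm(k, mean = 0, sd = jitter_ppm_sd) * 1e-6)
    mz_range <- if (k > 0) range(ion_mz) else c(100, 2000)
    if (diff(mz_range) <= 0) mz_range <- mz_range + c(-50, 50)
    noise_mz <- stats::runif(n_noise_peaks, mz_range[1], mz_range[2])
    peaks <- data.frame(
      mz = c(ion_mz, noise_mz),
      intensity = c(stats::runif(k, 0.2, 1),
                    stats::runif(n_noise_peaks, 0, 0.1))
    )
    truth <- data.frame(
      series = theo$series[emit], index = theo$index[emit],
      charge = theo$charge[emit], theo_mz = theo$mz[emit],
      peak_index = seq_len(k)
    )
    list(peaks = peaks, truth = truth)
  })
}
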