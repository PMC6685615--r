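Package: modscanr
Title: Mining Modification-Site Databases for Lysine Methylation in
    RAS-Superfamily GTPases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining post-translational modification (PTM) site
    databases distributed as delimiter-separated-value tables. Reads
    PhosphoSitePlus-style modification-site datasets, scans them for lysine
    methylation (mono-, di-, tri-) within a curated RAS-superfamily gene
    catalog, maps discovered sites to reference-equivalent residue positions
    (HRAS numbering) by global pairwise alignment, and validates
    methylated-peptide assignments through theoretical b/y fragment-ion
    monoisotopic masses, site-determining ions and ppm-tolerance peak
    matching. Includes seeded synthetic-data generators that plant
    ground-truth sites among decoy records so the whole workflow is testable
    without access to licence-restricted databases, and a command-line
    interface over the scan, mapping, fragment and simulation steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
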