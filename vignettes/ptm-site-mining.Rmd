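---
title: "Mining modification-site databases for lysine methylation in small GTPases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining modification-site databases for lysine methylation in small GTPases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modscanr)
```

## The problem

Lysine residues in the core G domain of RAS-superfamily GTPases — among
them Lys-5, Lys-16, Lys-117 and Lys-147 in HRAS numbering — are subject to
post-translational modification (ubiquitylation, acetylation and, less
explored, mono-, di- and trimethylation). Public PTM repositories such as
PhosphoSitePlus distribute their site evidence as large
delimiter-separated-value (DSV) tables: one row per (protein, residue,
modification) with a gene symbol, accession, a modification code like
`K5-m2`, and a ±7-residue flanking window. Asking "which lysine
methylation sites fall in the RAS superfamily?" is then a keyword scan
over tens of thousands of rows — easy to do, easy to do subtly wrong
(superstring gene-symbol hits, double-counted sites, silent row loss).

`modscanr` implements that scan as a tested library: DSV parsing with an
explicit dialect and a full accounting of rejected rows, a curated
RAS-superfamily keyword catalog, a filterable scanner with deduplicated
site summaries, residue-equivalence mapping of discovered sites onto a
reference numbering via global alignment, and theoretical b/y fragment-ion
machinery to validate methylated-peptide assignments against observed MS2
peaks. A seeded synthetic-data generator makes every step testable without
redistributing the licence-restricted source database.

## The DSV dialect

The public dataset's schema is not formally documented, so the reader is
parameterized by a `dsv_dialect()`: delimiter (tab by default), a preamble
policy, and a column map. The default preamble policy is `"auto"` — skip
lines until one contains all required column headers — because the public
files ship with a short free-text banner of varying length. The default
column map targets the public headers (`GENE`, `ACC_ID`, `MOD_RSD`,
`ORGANISM`, `SITE_+/-7_AA`, `PROTEIN`); both are overridable.

Parsing is total: a malformed body row (missing required field, a
modification code outside the `<residue><position>-<class>` grammar, a
flanking window whose center letter contradicts the coded residue) is
reported with its line number and reason, never silently dropped, and
`parsed + rejected = total` always holds. Unknown modification-class
tokens are preserved as `other:<token>` rather than rejected, so scanning
does not depend on a closed vocabulary. Positions are 1-based everywhere,
matching the field's "Lys-5" usage; flanking windows pad past the protein
termini with `_`.

## The gene catalog and matching semantics

The packaged catalog (`load_ras_superfamily_catalog()`) is a transcription
of a curated RAS-superfamily symbol-and-synonym list: 273 entries spanning
the RAS, RHO, RAB, RAN, ARF, and related families; one entry (ARHH) is
printed twice in the source table and collapses in the normalized view
(272 unique symbols), and a stray trailing period on `RABL5.` was stripped
at transcription. No synonym expansion beyond the printed table is
performed, and no live resolution against HGNC/NCBI is attempted — the
catalog is a fixed, reproducible input.

The scanner's default match mode is **case-insensitive exact equality**
on the gene symbol. This is a deliberate design choice: substring matching
would silently include superstring symbols — `HRASLS` (an HRAS-like
phospholipase, not a GTPase) is the canonical trap when scanning for
`HRAS`. Substring and regular-expression modes remain available for
motif-style keywords. Modification-class, residue and organism filters
compose conjunctively with the keyword clause. Organism filtering is off
by default — the natural scan is cross-species, and the effective
configuration is echoed into every JSON summary so a count can always be
traced back to its query.

Summaries deduplicate sites by the key `(accession, position, mod_class)`:
public datasets can repeat one site across evidence rows, and "n sites"
should count sites. Each deduplicated site is attributed to the normalized
gene symbol of its first matched row, which guarantees
`sum(per_gene) == distinct_sites` even if a site recurs under variant
spellings. Output preserves input row order; no sorting is applied.

## Residue equivalence by global alignment

"The position equivalent to Lys-5" is defined by the non-gap columns of a
global pairwise alignment between a homolog and the reference. The
alignment is Needleman–Wunsch with affine gaps — BLOSUM62, gap open 10,
gap extend 1, a gap run of length L costing `open + L * extend` — computed
by `Biostrings::pairwiseAlignment()`. These are the field's standard
defaults; nothing in the mapping depends delicately on them, and the
dynamic program is cross-checked in the test suite against an
exhaustive-enumeration oracle on short sequences. Terminal gaps are
penalized like internal gaps (true global alignment); tie-breaking among
co-optimal alignments is delegated to the alignment engine, which is
deterministic — the property the downstream golden tests actually need.

Homologs are aligned pairwise to the reference (a star topology) rather
than through a progressive multiple alignment: equivalence labels only
require homolog↔reference maps, pairwise alignments keep every map
independently verifiable, and no MSA heuristics enter the contract. The
position map induced by an alignment is strictly increasing in both
coordinates and bijective between the mapped subsets; a homolog position
aligned to a reference gap has no equivalent (`NA`), and a record whose
accession has no sequence is labeled `unmapped`, never dropped.

Column conservation counts homologs lacking an equivalent position in the
denominator — a deletion is non-conservation, not missing data. An empty
homolog set is an error (the fraction is undefined).

## Fragment-ion masses

All masses are monoisotopic; atomic masses, the proton (1.007276 Da) and
water (18.010565 Da) are pinned constants so ion tables are bit-stable.
A peptide's neutral mass is the sum of residue masses plus water plus the
modification deltas. For a peptide of length n, `b_i` covers positions
1..i (neutral mass: residues 1..i plus mods at positions ≤ i) and `y_j`
covers positions n−j+1..n plus water; `m/z = (neutral + z·proton)/z`. The
identity `mz(b_i, 1+) + mz(y_{n−i}, 1+) = M + 2 × 1.007276` holds
algebraically and is enforced to 1e-6 Da over random peptides in the
tests.

Two modification dictionaries are provided. The **chemical** dictionary
(default) derives deltas from elemental composition: methyl = CH2
(14.01565), dimethyl = C2H4 (28.03130), trimethyl = C3H6 (42.04695),
acetyl = C2H2O (42.01057). The **paper-parameter** dictionary stores,
verbatim, a set of deltas as printed in a legacy search-engine parameter
listing: +14.0156, +28.0106, +42.0106. These printed values are internally
inconsistent with methyl chemistry — the dimethyl value is not 2×CH2, the
trimethyl value coincides with the acetyl delta, and the monomethyl value
is a truncation (not a rounding) of 14.015650. The dictionary exists so
results computed under those parameters can be reproduced exactly;
`modscanr` does not endorse an interpretation, and the mode flag changes
only modification deltas, never residue masses.

Site-determining ions for a single variable modification are computed as
the series difference between the assigned and an alternative placement —
exactly the ions a manual validation would inspect. Peak matching is
greedy nearest-match in relative (ppm) error, each observed peak used at
most once, with candidate pairs ranked by absolute ppm error so the result
is invariant to observed-peak order. Greedy matching (rather than optimal
bipartite assignment) is standard practice and adequate at the 5–20 ppm
tolerances where high-resolution instruments operate.

## The synthetic-data generator

`generate_site_dataset()` emulates the *structure* of a
methylation-centric modification-site snapshot: a short banner, the
default header, and n body rows in which planted catalog-gene
lysine-methylation sites are interleaved uniformly at random among decoy
rows. Decoys draw gene symbols from a packaged pool of 291 common human
symbols checked disjoint from the catalog (including the `HRASLS`
near-miss), modification classes from a mix chosen to resemble a
methylation dataset with minor contaminating classes (m1 0.50, m2 0.20,
m3 0.10, ac 0.08, ub 0.07, p 0.05), residues consistent with class (K/R
for methyl, K for acetyl/ubiquityl, S/T/Y for phospho), an organism mix of
human/mouse/rat at 0.7/0.2/0.1, and flanking windows consistent with
residue and position. One integer seed drives a named PRNG stream per
generator (Mersenne-Twister, kinds pinned), so output is byte-identical
across platforms and adding a generator never shifts existing fixtures.

What the generator does **not** emulate: real gene-symbol ambiguity and
cross-species synonymy, evidence-count and literature-reference fields,
the true positional and flanking-sequence statistics of curated sites, or
correlated duplication of sites across rows. Consequently, a perfect
sensitivity/precision result on generator output demonstrates that the
scan machinery is correct — exact matching, filtering, deduplication and
counting do what they claim — not that any particular biological count
from a live database snapshot is recoverable; those counts depend on the
snapshot version and its curation.

`generate_peak_list()` emulates a CID MS2 spectrum of a modified peptide:
a uniformly sampled subset of the theoretical 1+ b/y ions of size
`round(coverage × (2n−2))`, Gaussian ppm jitter, and uniform noise peaks
over the observed m/z range, with a ground-truth ion→peak map. It does not
model isotope envelopes, neutral losses, a/c/x/z ions, intensity
structure, or charge states above those requested.

## Numerical and design choices

* Mass constants are frozen in the package rather than taken from a
  dependency, so golden ion tables cannot drift with a library upgrade.
* `modification_delta()` rounds with R's standard rounding when asked for
  fixed decimals; full precision is the default.
* Site keys use an unprintable separator internally to avoid collisions
  with field text.
* Degenerate inputs are first-class: empty keyword lists match nothing
  unless filters-only scanning is requested explicitly (the CLI refuses an
  empty keyword file without `--allow-filters-only`); zero scan matches is
  a successful run (exit 0); an empty record list writes a header-only
  file; a peptide of length 1 has a neutral mass but no fragment series.
* Test problem sizes were chosen to exercise the contracts densely while
  keeping the default suite fast: scanner/oracle equivalence on 100 random
  dataset–query pairs (datasets up to 800 rows; the planted-recovery check
  runs at 10,000 rows), alignment/enumeration equivalence on 500 random
  pairs of length ≤ 6 (exhaustive enumeration grows as the Delannoy
  numbers), fragment identities on 1,000 random peptides of length 2–25,
  and peak-recovery over 100 seeded spectra.

## Limitations

* The scanner is an exact/substring/regex matcher, not a fuzzy one: it
  will not bridge edit-distance variants or resolve retired gene symbols.
* Residue equivalence is sequence-based; structurally equivalent positions
  that global alignment misplaces (e.g. in long, divergent insertions)
  are out of reach, and no G-box motif discovery is attempted.
* Fragment machinery is deliberately minimal: monoisotopic b/y series
  only. It validates site assignments; it does not compete with a database
  search engine and computes no identification scores or FDR.
* Conservation figures computed over small homolog panels are descriptive
  of that panel only; they are not estimates of superfamily-wide
  conservation unless the panel is representative.
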