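# Peptide masses, b/y series, site-determining ions and peak matching.

test_that("neutral masses match standard monoisotopic values", {
  # glycine residue + water, cross-checked against standard tables
  expect_equal(peptide_neutral_mass(modified_peptide("G")), 75.03203,
               tolerance = 1e-7)
  expect_error(peptide_neutral_mass(modified_peptide("GX")), "illegal")
})

test_that("chemical-mode deltas reproduce elemental sums", {
  mods <- builtin_mods("chemical")
  expect_equal(modification_delta(mods$methyl), 14.01565, tolerance = 1e-5)
  expect_equal(modification_delta(mods$dimethyl), 28.03130, tolerance = 1e-5)
  expect_equal(modification_delta(mods$trimethyl), 42.04695, tolerance = 1e-5)
  expect_equal(modification_delta(mods$acetyl), 42.01057, tolerance = 1e-5)
  expect_equal(modification_delta(mod_spec("none", c(C = 0))), 0)
})

test_that("paper-parameter mode stores the printed deltas verbatim", {
  mods <- builtin_mods("paper-parameter")
  expect_identical(modification_delta(mods$methyl), 14.0156)
  expect_identical(modification_delta(mods$dimethyl), 28.0106)
  expect_identical(modification_delta(mods$trimethyl), 42.0106)
  # the printed trimethyl value coincides with the acetyl elemental delta
  expect_equal(modification_delta(builtin_mods("chemical")$acetyl, 4),
               42.0106)
})

test_that("mass is additive in modifications", {
  pep0 <- modified_peptide("MTEYKLVVVG")
  pep1 <- modified_peptide("MTEYKLVVVG",
                           list(list(position = 5L,
                                     spec = builtin_mods()$dimethyl)))
  expect_equal(peptide_neutral_mass(pep1) - peptide_neutral_mass(pep0),
               28.03130, tolerance = 1e-5)
})

test_that("series have n-1 ions per series per charge and known y1 values", {
  fs <- fragment_series(modified_peptide("GK"), max_charge = 1)
  expect_identical(nrow(fs), 2L)
  # y1 of ..K: K residue + water + proton
  expect_equal(fs$mz[fs$series == "y" & fs$index == 1], 147.11280,
               tolerance = 1e-5)
  fs3 <- fragment_series(modified_peptide("MTEYK"), max_charge = 3)
  expect_identical(nrow(fs3), 24L)  # 2 series x 4 indices x 3 charges
  expect_identical(sum(fs3$series == "b" & fs3$charge == 2), 4L)
  expect_error(fragment_series(modified_peptide("G")), "length >= 2")
})

test_that("b/y complementarity holds and mods shift exactly the covering ions", {
  pep <- parse_peptide_string("MTEYK[dimethyl]LVVVGAGGVGK")
  n <- nchar(pep$sequence)
  fs <- fragment_series(pep, max_charge = 1)
  b <- fs[fs$series == "b", ]
  y <- fs[fs$series == "y", ]
  for (i in seq_len(n - 1)) {
    expect_equal(b$mz[b$index == i] + y$mz[y$index == n - i],
                 peptide_neutral_mass(pep) + 2 * 1.007276,
                 tolerance = 1e-6)
  }
  # mod at position 5 (length 16): y_j covers it iff j >= 12; b_i iff i >= 5
  fs0 <- fragment_series(modified_peptide(pep$sequence), max_charge = 1)
  d <- modification_delta(builtin_mods()$dimethyl)
  shift <- fs$mz - fs0$mz
  covered <- (fs$series == "b" & fs$index >= 5) |
    (fs$series == "y" & fs$index >= 12)
  expect_equal(shift[covered], rep(d, sum(covered)), tolerance = 1e-9)
  expect_equal(shift[!covered], rep(0, sum(!covered)), tolerance = 1e-12)
  expect_identical(fs$carries_mods[covered], rep("5", sum(covered)))
  expect_identical(fs$carries_mods[!covered], rep("", sum(!covered)))
})

test_that("site-determining ions are the series diff of the two placements", {
  methyl <- builtin_mods()$methyl
  pep <- modified_peptide("AKAKA", list(list(position = 2L, spec = methyl)))
  ions <- site_determining_ions(pep, 4L)
  expect_identical(paste0(ions$series, ions$index),
                   c("b2", "b3", "y2", "y3"))
  pep2 <- modified_peptide("KK", list(list(position = 1L, spec = methyl)))
  ions2 <- site_determining_ions(pep2, 2L)
  expect_identical(paste0(ions2$series, ions2$index), c("b1", "y1"))
  expect_identical(nrow(site_determining_ions(pep, 2L)), 0L)
  two <- modified_peptide("AKAKA", list(list(position = 2L, spec = methyl),
                                        list(position = 4L, spec = methyl)))
  expect_error(site_determining_ions(two, 2L), "exactly one")
})

test_that("peak matching is greedy within tolerance and order-invariant", {
  pep <- modified_peptide("MTEYKLVVVG")
  theo <- fragment_series(pep, max_charge = 1)
  obs <- data.frame(mz = theo$mz, intensity = 1)
  m <- match_peaks(theo, obs, tolerance_ppm = 10)
  expect_equal(m$coverage, 1.0)

  # one peak 50 ppm off at 10 ppm tolerance matches nothing
  one <- data.frame(mz = theo$mz[1] * (1 + 50e-6), intensity = 1)
  expect_equal(match_peaks(theo[1, ], one, tolerance_ppm = 10)$coverage, 0)

  # each observed peak is used at most once
  dup <- data.frame(mz = rep(theo$mz[1], 1), intensity = 1)
  two_ions <- theo[c(1, 1), ]
  expect_equal(match_peaks(two_ions, dup, tolerance_ppm = 10)$coverage, 0.5)

  # invariance to observed-peak order
  set.seed(5)
  jit <- data.frame(mz = theo$mz * (1 + runif(nrow(theo), -5e-6, 5e-6)),
                    intensity = runif(nrow(theo)))
  m1 <- match_peaks(theo, jit, tolerance_ppm = 10)
  perm <- sample(nrow(jit))
  m2 <- match_peaks(theo, jit[perm, ], tolerance_ppm = 10)
  expect_equal(m1$coverage, m2$coverage)
  o1 <- m1$matched[order(m1$matched$series, m1$matched$index), ]
  o2 <- m2$matched[order(m2$matched$series, m2$matched$index), ]
  expect_equal(o1$obs_mz, o2$obs_mz)
})

test_that("the bracket syntax parses and reports malformed input by offset", {
  pep <- parse_peptide_string("MTEYK[dimethyl]LVVVGAGGVGK")
  expect_identical(pep$sequence, "MTEYKLVVVGAGGVGK")
  expect_identical(pep$mods[[1]]$position, 5L)
  expect_identical(pep$mods[[1]]$spec$name, "dimethyl")
  expect_error(parse_peptide_string("MTEYK[dimethyl"), "offset 6")
  expect_error(parse_peptide_string("[methyl]GK"), "offset 1")
  expect_error(parse_peptide_string("GK[nosuchmod]"), "unknown modification")
  expect_error(parse_peptide_string("G1K"), "offset 2")
})

test_that("peak lists round trip through TSV", {
  peaks <- data.frame(mz = c(147.11280, 58.02874), intensity = c(1, 0.5))
  path <- tempfile(fileext = ".tsv")
  write_peak_list(peaks, path)
  back <- read_peak_list(path)
  expect_equal(back$mz, peaks$mz, tolerance = 1e-6)
  expect_equal(back$intensity, peaks$intensity, tolerance = 1e-6)
})
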