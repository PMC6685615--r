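# Modification-site DSV reading, writing and the mod-code grammar.

write_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

header <- "GENE\tACC_ID\tMOD_RSD\tORGANISM\tSITE_+/-7_AA\tPROTEIN"

test_that("mod-code grammar parses valid codes and rejects bad ones", {
  cases <- list(
    list(code = "K147-m1", residue = "K", position = 147L, mod_class = "m1"),
    list(code = "K5-m2", residue = "K", position = 5L, mod_class = "m2"),
    list(code = "S33-p", residue = "S", position = 33L, mod_class = "p"),
    list(code = "K9-me9", residue = "K", position = 9L,
         mod_class = "other:me9")  # unknown token preserved, not rejected
  )
  for (cs in cases) {
    p <- parse_mod_code(cs$code)
    expect_true(p$ok, info = cs$code)
    expect_identical(p$residue, cs$residue)
    expect_identical(p$position, cs$position)
    expect_identical(p$mod_class, cs$mod_class)
  }
  for (bad in list("X0-zz", "", "K0-m1", "B12-m1", "K5", "5K-m1", "K-5-m1")) {
    p <- parse_mod_code(bad)
    expect_false(p$ok, info = bad)
    expect_true(nzchar(p$reason))
  }
})

test_that("reader locates the header behind 0-10 preamble lines", {
  body <- c("HRAS\tP01112\tK5-m2\thuman\t\tGTPase HRas",
            "RAN\tP62826\tK37-m1\thuman\t\tGTPase Ran")
  baseline <- NULL
  for (n_pre in 0:10) {
    pre <- if (n_pre > 0) paste("banner line", seq_len(n_pre)) else character(0)
    path <- write_fixture(c(pre, header, body))
    ds <- read_site_dataset(path)
    expect_identical(ds$report$row_count_parsed, 2L)
    expect_identical(nrow(ds$report$rejected), 0L)
    recs <- ds$records
    recs$source_row <- NULL  # line numbers shift with the preamble
    if (is.null(baseline)) baseline <- recs else expect_identical(recs, baseline)
  }
  # explicit numeric preamble skip works too
  path <- write_fixture(c("x", "y", "z", header, body))
  ds <- read_site_dataset(path, dsv_dialect(preamble = 3))
  expect_identical(ds$report$row_count_parsed, 2L)
})

test_that("code fields parse into residue/position/class", {
  path <- write_fixture(c(header, "HRAS\tP01112\tK5-m2\thuman\t\tx"))
  r <- read_site_dataset(path)$records
  expect_identical(r$residue, "K")
  expect_identical(r$position, 5L)
  expect_identical(r$mod_class, "m2")
})

test_that("malformed rows are reported with line numbers, never dropped", {
  set.seed(42)
  n <- 100L
  genes <- sample(c("HRAS", "RAN", "TP53"), n, replace = TRUE)
  codes <- sprintf("K%d-m1", sample(1:200, n, replace = TRUE))
  corrupt_at <- c(7L, 23L, 55L, 91L)
  codes[corrupt_at] <- c("X0-zz", "notacode", "K0-m1", "B5-m2")
  lines <- c(header, sprintf("%s\tP%05d\t%s\thuman\t\tx", genes, 1:n, codes))
  path <- write_fixture(lines)
  ds <- read_site_dataset(path)

  # independent line-by-line hand filter on the same fixture
  ok_by_hand <- vapply(codes, function(cd) parse_mod_code(cd)$ok, logical(1))
  expect_identical(ds$report$row_count_total, n)
  expect_identical(ds$report$row_count_parsed, sum(ok_by_hand))
  expect_identical(ds$report$row_count_parsed +
                     nrow(ds$report$rejected), n)
  expect_identical(ds$report$rejected$line, corrupt_at + 1L)
  expect_identical(ds$report$row_count_parsed, 96L)
})

test_that("flank-window integrity is enforced on read", {
  ok <- "HRAS\tP01112\tK8-m1\thuman\tAAAAAAAKAAAAAAA\tx"
  bad_center <- "HRAS\tP01112\tK8-m1\thuman\tAAAAAAARAAAAAAA\tx"
  bad_len <- "HRAS\tP01112\tK8-m1\thuman\tAKA\tx"
  ds <- read_site_dataset(write_fixture(c(header, ok, bad_center, bad_len)))
  expect_identical(ds$report$row_count_parsed, 1L)
  expect_match(ds$report$rejected$reason[1], "center")
  expect_match(ds$report$rejected$reason[2], "15 characters")
})

test_that("a missing required column is a hard error naming the column", {
  path <- write_fixture(c("GENE\tACC_ID\tWRONG", "HRAS\tP01112\tK5-m2"))
  expect_error(read_site_dataset(path), "MOD_RSD")
  expect_error(read_site_dataset(tempfile()), "cannot read")
})

test_that("gzip-compressed input parses identically to plain text", {
  lines <- c(header, "HRAS\tP01112\tK5-m2\thuman\t\tx",
             "RAN\tP62826\tK37-m1\thuman\t\tx")
  plain <- write_fixture(lines)
  gz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "wb")
  writeLines(lines, con)
  close(con)
  expect_identical(read_site_dataset(gz)$records,
                   read_site_dataset(plain)$records)
})

test_that("write then read is the identity on all semantic fields", {
  set.seed(7)
  recs <- random_records(10)
  recs$flank_window <- vapply(seq_len(10), function(i) {
    w <- paste(sample(AA_LETTERS, 15, replace = TRUE), collapse = "")
    substr(w, 8, 8) <- recs$residue[i]
    w
  }, character(1))
  path <- tempfile(fileext = ".tsv")
  n <- write_records(recs, path)
  expect_identical(n, 10L)
  back <- read_site_dataset(path)$records
  for (col in c("gene_symbol", "accession", "organism", "residue",
                "position", "mod_class", "flank_window", "protein_name")) {
    expect_identical(back[[col]], recs[[col]], info = col)
  }
})

test_that("non-ASCII protein names survive a round trip byte-identically", {
  recs <- hras_fixture()[1:2, ]
  recs$protein_name <- c("GTPase β-subunit", "Ras–related")
  p1 <- tempfile(); p2 <- tempfile()
  write_records(recs, p1)
  back <- read_site_dataset(p1)$records
  expect_identical(back$protein_name, recs$protein_name)
  write_records(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("an empty record list writes a header-only file", {
  path <- tempfile()
  expect_identical(write_records(hras_fixture()[0, ], path), 0L)
  expect_identical(length(readLines(path)), 1L)
  ds <- read_site_dataset(path)
  expect_identical(ds$report$row_count_total, 0L)
})
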