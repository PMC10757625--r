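test_that("library loads the five fields and preserves record order", {
  f <- write_tsv_fixture(c(
    "biopeptide_ID\tbiopeptid_name\tpeptide_sequence\tchemical_mass\tbiological_activity_category",
    "B1\talpha\tIPP\t325.41\tACE inhibitor",
    "B2\tbeta\tVPP\t311.38\tACE inhibitor",
    "B3\tgamma\tIPI\t341.45\tDPP-4 inhibitor",
    "B4\tdelta\tWV\t303.36\tDPP-4 inhibitor;antioxidative",
    "B5\tepsilon\tYGGFL\t555.63\topioid"))
  lib <- load_library(f)
  expect_s3_class(lib, "biopeptide_library")
  expect_equal(nrow(lib), 5L)
  expect_equal(lib$peptide_id, c("B1", "B2", "B3", "B4", "B5"))
  expect_equal(lib$sequence[1], "IPP")
  expect_equal(lib$mass[3], 341.45)
  # multi-activity cell split on ';'
  expect_equal(lib$activities[[4]], c("DPP-4 inhibitor", "antioxidative"))
  expect_false(any(lib$out_of_range))
})

test_that("header-only file gives an empty library", {
  f <- write_tsv_fixture("id\tname\tsequence\tmass\tactivity")
  lib <- load_library(f)
  expect_equal(nrow(lib), 0L)
})

test_that("canonical and paper-style headers map to the same fields", {
  a <- load_library(write_tsv_fixture(c(
    "id\tname\tsequence\tmass\tactivity", "B1\tx\tIPP\t325.41\tACE inhibitor")))
  b <- load_library(write_tsv_fixture(c(
    "Biopeptide_ID\tBiopeptid_name (biological role)\tPeptide sequence\tChemical mass\tBiological activity category",
    "B1\tx\tIPP\t325.41\tACE inhibitor")))
  expect_equal(a$sequence, b$sequence)
  expect_equal(a$mass, b$mass)
  expect_equal(a$activities, b$activities)
})

test_that("non-standard residues are a strict error naming the culprit", {
  f <- write_tsv_fixture(c("id\tname\tsequence\tmass\tactivity",
                           "B1\tx\tAZQ\t100\tfoo"))
  expect_error(load_library(f, strict = TRUE), "Z")
  expect_message(lenient <- load_library(f, strict = FALSE), "skipped 1")
  expect_equal(nrow(lenient), 0L)
})

test_that("length bounds 2-60 gate records unless overridden", {
  f <- write_tsv_fixture(c("id\tname\tsequence\tmass\tactivity",
                           "B1\tx\tG\t\tfoo",
                           "B2\tx\tGG\t\tfoo",
                           paste0("B3\tx\t", strrep("G", 61), "\t\tfoo")))
  expect_error(load_library(f, strict = TRUE), "2-60")
  expect_message(lenient <- load_library(f, strict = FALSE), "skipped 2")
  expect_equal(lenient$peptide_id, "B2")
  all3 <- load_library(f, allow_out_of_range = TRUE)
  expect_equal(nrow(all3), 3L)
  expect_equal(all3$out_of_range, c(TRUE, FALSE, TRUE))
})

test_that("duplicate peptide ids and missing columns are rejected", {
  dup <- write_tsv_fixture(c("id\tname\tsequence\tmass\tactivity",
                             "B1\tx\tIPP\t\tfoo", "B1\ty\tVPP\t\tfoo"))
  expect_error(load_library(dup), "duplicate peptide_id")
  noseq <- write_tsv_fixture(c("id\tname\tmass", "B1\tx\t100"))
  expect_error(load_library(noseq), "sequence")
})

test_that("library round-trips through delimited text field-identically", {
  lib <- load_library(system.file("extdata", "example_library.tsv",
                                  package = "biopepscan"))
  f <- tempfile(fileext = ".tsv")
  write_library(lib, f)
  back <- load_library(f)
  for (col in c("peptide_id", "name", "sequence", "mass"))
    expect_equal(back[[col]], lib[[col]])
  expect_equal(back$activities, lib$activities)
  # CSV dialect too
  fcsv <- tempfile(fileext = ".csv")
  write_library(lib, fcsv)
  expect_equal(load_library(fcsv)$sequence, lib$sequence)
})

test_that("proteome FASTA parsing: ids, case, stop stripping, multi-line", {
  f <- write_tsv_fixture(c(">p1 first protein", "MKV", ">p2", "GG"),
                         ext = ".fasta")
  prot <- load_proteome(f)
  expect_equal(prot$protein_id, c("p1", "p2"))
  expect_equal(prot$description, c("first protein", ""))
  expect_equal(nchar(prot$sequence), c(3L, 2L))

  f2 <- write_tsv_fixture(c(">p1", "mkvr*"), ext = ".fasta")
  expect_equal(load_proteome(f2)$sequence, "MKVR")

  # multi-line sequence is concatenated; internal '*' retained
  f3 <- write_tsv_fixture(c(">p1", "MKV", "R*G"), ext = ".fasta")
  expect_equal(load_proteome(f3)$sequence, "MKVR*G")
})

test_that("proteome loader flags duplicates, emptiness and nucleotide content", {
  fdup <- write_tsv_fixture(c(">p1", "MKV", ">p1", "GG"), ext = ".fasta")
  expect_error(load_proteome(fdup), "duplicate protein_id")
  fempty <- tempfile(fileext = ".fasta"); file.create(fempty)
  expect_warning(p <- load_proteome(fempty), "empty")
  expect_equal(nrow(p), 0L)
  fnuc <- write_tsv_fixture(c(">c1", "ACGTACGTACGTACGTACGTN"), ext = ".fasta")
  expect_warning(load_proteome(fnuc), "nucleotide")
  expect_error(load_proteome(tempfile()), "not found",
               class = "biopepscan_io_error")
})

test_that("expression table: parsing, rejection of non-numeric rows, schema", {
  f <- write_tsv_fixture(c("gene_id\tlog2fc", "gA\t1.5", "gB\t-2.0"))
  e <- load_expression(f)
  expect_equal(e$gene_id, c("gA", "gB"))
  expect_equal(e$log2fc, c(1.5, -2.0))

  fna <- write_tsv_fixture(c("gene_id\tlog2fc", "gA\t1.5", "gC\tNA"))
  expect_message(e2 <- load_expression(fna), "rows 2")
  expect_equal(e2$gene_id, "gA")

  expect_equal(nrow(load_expression(
    write_tsv_fixture("gene_id\tlog2fc"))), 0L)
  expect_error(load_expression(write_tsv_fixture(c("gene\tfc", "gA\t1"))),
               "log2fc", class = "biopepscan_validation_error")
})

test_that("peptide mass: worked values, both modes, error cases", {
  expect_equal(compute_peptide_mass("G"), 75.07, tolerance = 0.01 / 75)
  expect_equal(compute_peptide_mass("GG"), 132.12, tolerance = 0.01 / 132)
  # monoisotopic differs from average beyond rounding
  expect_lt(compute_peptide_mass("WR", "monoisotopic"),
            compute_peptide_mass("WR", "average"))
  expect_error(compute_peptide_mass(""), "empty")
  expect_error(compute_peptide_mass("GXG"), "X")
})

test_that("peptide mass is additive up to one water", {
  set.seed(11)
  water <- 18.01528
  for (i in 1:25) {
    s1 <- paste(sample(standard_residues(), sample(1:20, 1), TRUE), collapse = "")
    s2 <- paste(sample(standard_residues(), sample(1:20, 1), TRUE), collapse = "")
    expect_equal(compute_peptide_mass(paste0(s1, s2)),
                 compute_peptide_mass(s1) + compute_peptide_mass(s2) - water,
                 tolerance = 1e-9)
  }
})

test_that("mass validation reports discrepancies and missing masses only", {
  lib <- biopeptide_library(
    peptide_id = c("ok", "bad", "none"),
    name = "x", sequence = c("GG", "GG", "GG"),
    mass = c(132.12, 500.0, NA), activities = list("a", "a", "a"))
  rep <- validate_library_masses(lib, tolerance = 0.5)
  expect_equal(rep$discrepancies$peptide_id, "bad")
  expect_equal(rep$discrepancies$delta, 500 - 132.119, tolerance = 1e-3)
  expect_equal(rep$missing_mass, "none")
  # both mass conventions are reported for the flagged record
  expect_true(all(c("computed_average", "computed_monoisotopic") %in%
                  names(rep$discrepancies)))
})
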