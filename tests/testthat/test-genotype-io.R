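# Dialect parsing, canonical coding and round-trips.

tiny_ab_file <- function() {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("accession\tm1\tm2\tm3",
               "ACC1\tA\tB\tH",
               "ACC2\tB\tA\tNA",
               "ACC3\tH\tB\tA"), path)
  path
}

test_that("AB dialect maps tokens onto the four canonical states", {
  gm <- read_genotype_matrix(tiny_ab_file(), genotype_dialect("AB"))
  expect_identical(dim(gm), c(3L, 3L))
  expect_identical(calls(gm)["ACC1", ], c(m1 = 0L, m2 = 2L, m3 = 1L))
  expect_identical(calls(gm)["ACC2", "m3"], NA_integer_)
  expect_identical(accessions(gm), c("ACC1", "ACC2", "ACC3"))
})

test_that("the same calls read under different dialects coincide", {
  ab <- tiny_ab_file()
  dos <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tm1\tm2\tm3",
               "ACC1\t0\t2\t1",
               "ACC2\t2\t0\tNA",
               "ACC3\t1\t2\t0"), dos)
  pair <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tm1\tm2\tm3",
               "ACC1\tAA\tBB\tAB",
               "ACC2\tBB\tAA\tNA",
               "ACC3\tAB\tBB\tAA"), pair)
  gm_ab <- read_genotype_matrix(ab, genotype_dialect("AB"))
  gm_dos <- read_genotype_matrix(dos, genotype_dialect("DOSAGE"))
  gm_pair <- read_genotype_matrix(pair, genotype_dialect("PAIR"))
  expect_identical(calls(gm_ab), calls(gm_dos))
  expect_identical(calls(gm_ab), calls(gm_pair))
})

test_that("nucleotide dialect assigns the alphabetically first allele as reference", {
  path <- withr::local_tempfile()
  writeLines(c("accession\tm1\tm2",
               "ACC1\tG/G\tT/T",
               "ACC2\tG/T\tC/C",
               "ACC3\tT/T\tC/T"), path)
  gm <- read_genotype_matrix(path, genotype_dialect("NUCLEOTIDE"))
  expect_identical(calls(gm)[, "m1"], c(ACC1 = 0L, ACC2 = 1L, ACC3 = 2L))
  # m2: C < T so C is reference -> T/T is HOM_ALT
  expect_identical(calls(gm)[, "m2"], c(ACC1 = 2L, ACC2 = 0L, ACC3 = 1L))
  expect_identical(marker_meta(gm)$allele_ref, c("G", "C"))
  # explicit allele_ref overrides the alphabetical rule
  gm2 <- read_genotype_matrix(path, genotype_dialect("NUCLEOTIDE"),
                              marker_meta = data.frame(allele_ref = c("T", "C")))
  expect_identical(calls(gm2)[, "m1"], c(ACC1 = 2L, ACC2 = 1L, ACC3 = 0L))
})

test_that("round-trip write/read is the identity in every writable dialect", {
  set.seed(42)
  gm <- rand_gm(50, 20, p_het = 0.05, p_missing = 0.05)
  for (coding in c("AB", "PAIR", "DOSAGE")) {
    for (orient in c("accessions_in_rows", "markers_in_rows")) {
      d <- genotype_dialect(coding, delimiter = ",", orientation = orient)
      path <- withr::local_tempfile()
      write_genotype_matrix(gm, path, d)
      back <- read_genotype_matrix(path, d)
      expect_identical(calls(back), calls(gm))
    }
  }
  # nucleotide needs allele metadata
  mm <- data.frame(allele_ref = rep("A", 20), allele_alt = rep("G", 20))
  gm_nt <- genotype_matrix(calls(gm), marker_meta = mm)
  d <- genotype_dialect("NUCLEOTIDE")
  path <- withr::local_tempfile()
  write_genotype_matrix(gm_nt, path, d)
  expect_identical(calls(read_genotype_matrix(path, d)), calls(gm))
})

test_that("identity and coding violations raise classed errors", {
  dup <- withr::local_tempfile()
  writeLines(c("accession\tm1", "ACC1\tA", "ACC1\tB"), dup)
  expect_error(read_genotype_matrix(dup, genotype_dialect("AB")),
               class = "minmark_identity_error")
  bad <- withr::local_tempfile()
  writeLines(c("accession\tm1\tm2", "ACC1\tA\tZ"), bad)
  err <- expect_error(read_genotype_matrix(bad, genotype_dialect("AB")),
                      class = "minmark_coding_error")
  expect_match(conditionMessage(err), "Z")
  expect_match(conditionMessage(err), "ACC1")
  expect_match(conditionMessage(err), "m2")
  expect_error(genotype_matrix(matrix(0L, 2, 2), accession_ids = c("A", "A")),
               class = "minmark_identity_error")
})

test_that("degenerate matrices survive a round-trip", {
  empty <- genotype_matrix(matrix(integer(0), 0, 3,
                                  dimnames = list(NULL, c("m1", "m2", "m3"))))
  path <- withr::local_tempfile()
  write_genotype_matrix(empty, path)
  expect_identical(readLines(path), "accession\tm1\tm2\tm3")
  back <- read_genotype_matrix(path)
  expect_identical(dim(back), c(0L, 3L))
  # missing tokens are emitted as the configured token
  gm <- genotype_matrix(matrix(NA_integer_, 1, 1,
                               dimnames = list("ACC1", "m1")))
  d <- genotype_dialect("AB", missing_tokens = c("-", "NA"))
  write_genotype_matrix(gm, path, d)
  expect_match(readLines(path)[2], "-", fixed = TRUE)
  expect_identical(calls(read_genotype_matrix(path, d))[1, 1], NA_integer_)
})

test_that("VCF import maps GT fields and skips non-biallelic records", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1",
    "1\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.",
    "1\t300\ttri\tG\tA,T\t.\tPASS\t.\tGT\t0/0\t1/1",
    "1\t400\tindel\tG\tGA\t.\tPASS\t.\tGT\t0/0\t1/1"), vcf)
  expect_message(gm <- import_vcf(vcf), "skipped 2")
  expect_identical(dim(gm), c(2L, 2L))
  expect_identical(calls(gm)["S1", ], c(snp1 = 0L, snp2 = 1L))  # 0|1 phased HET
  expect_identical(calls(gm)["S2", ], c(snp1 = 2L, snp2 = NA_integer_))
  expect_identical(marker_meta(gm)$position_bp, c(100L, 200L))
})

test_that("panel files round-trip in order, with and without bookkeeping", {
  ids <- sprintf("MK%02d", 1:24)
  path <- withr::local_tempfile()
  write_panel(ids, path)
  expect_identical(read_panel(path)$markers, ids)

  gm <- rand_gm(10, 8)
  panel <- select_minimal_markers(gm)
  write_panel(panel, path)
  back <- read_panel(path)
  expect_identical(back$markers, panel$markers)
  expect_identical(unname(back$newly_resolved), unname(panel$newly_resolved))

  writeLines(character(0), path)
  expect_length(read_panel(path)$markers, 0)
  writeLines(c("m1", "m2", "m1"), path)
  expect_error(read_panel(path), class = "minmark_identity_error")
})
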