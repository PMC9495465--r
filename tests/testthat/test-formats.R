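# JASPAR PFM parsing -----------------------------------------------------

test_that("read_jaspar_pfm parses bracketed and bare rows", {
  lines <- c(">MX0001 TOY", "A [ 10 0 5 ]", "C [0 10 5]",
             "G [0 0 0]", "T [0 0 0]",
             ">MX0002 OTHER", "A 1 2", "C 3 4", "G 5 6", "T 7 8")
  pfms <- read_jaspar_pfm(lines)
  expect_length(pfms, 2)
  expect_equal(pfms[[1]]$matrix_id, "MX0001")
  expect_equal(pfms[[1]]$tf_name, "TOY")
  expect_equal(unname(pfms[[1]]$counts["A", ]), c(10, 0, 5))
  expect_equal(motif_width(pfms[[2]]), 2L)
  expect_equal(unname(pfms[[2]]$counts["T", ]), c(7, 8))
})

test_that("JASPAR write-read round-trips and errors name the matrix", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar_pfm(list(toy_pfm("MA0001.1", "TOY")), path)
  back <- read_jaspar_pfm(path)
  expect_equal(back[[1]]$counts, toy_pfm("MA0001.1", "TOY")$counts)
  expect_equal(back[[1]]$matrix_id, "MA0001.1")

  expect_error(
    read_jaspar_pfm(c(">BAD X", "A 1 2", "C 1 2", "G 1 2")),
    "BAD.*3 count rows", class = "rsnpscan_format_error")
  expect_error(
    read_jaspar_pfm(c(">RAGGED X", "A 1 2", "C 1", "G 1 2", "T 1 2")),
    "ragged", class = "rsnpscan_format_error")
  expect_error(
    read_jaspar_pfm(c(">NN X", "A x y", "C 1 2", "G 1 2", "T 1 2")),
    "not numeric", class = "rsnpscan_format_error")
  expect_error(read_jaspar_pfm(c("A 1 2", "C 1 2")), "header")
})

test_that("pfm() validates shape and counts", {
  expect_error(pfm("X", "X", matrix(1, 3, 4)), "4 rows")
  expect_error(pfm("X", "X", matrix(-1, 4, 2)), "negative")
  m <- matrix(1, 4, 2); m[, 2] <- 0
  expect_error(pfm("X", "X", m), "all-zero")
  # rownames in non-canonical order are reordered, not trusted positionally
  m2 <- matrix(c(5, 0, 0, 0), 4, 1, dimnames = list(c("T", "G", "C", "A")))
  expect_equal(unname(pfm("X", "X", m2)$counts["T", 1]), 5)
})

test_that("consensus takes the max-count base with A,C,G,T tie order", {
  expect_equal(consensus(toy_pfm()), "ACGT")
  tie <- pfm("T1", "T1", matrix(1, 4, 2))
  expect_equal(consensus(tie), "AA")
})

# SNP tables --------------------------------------------------------------

test_that("minimal-VCF dialect: biallelic record, maf and common flag", {
  tbl <- read_snp_table("chr1\t150\trs1\tG\tA\t.\t.\tAF=0.12",
                        dialect = "vcf_min")
  expect_equal(tbl$rsid, "rs1")
  expect_equal(tbl$pos, 150L)
  expect_equal(tbl$major, "G")
  expect_equal(tbl$minor, "A")
  expect_equal(tbl$maf, 0.12)
  expect_true(tbl$common)
  expect_equal(tbl$population, "ALL")
})

test_that("VCF ALT frequency above 0.5 swaps major and minor", {
  expect_message(
    tbl <- read_snp_table("chr1\t10\trs2\tC\tT\t.\t.\tAF=0.7",
                          dialect = "vcf_min"),
    "major")
  expect_equal(tbl$major, "T")
  expect_equal(tbl$minor, "C")
  expect_equal(tbl$maf, 0.3)
})

test_that("multi-allelic VCF records reduce to the most frequent ALT", {
  expect_message(
    tbl <- read_snp_table("chr1\t10\trs3\tA\tC,G\t.\t.\tAF=0.05,0.2",
                          dialect = "vcf_min"),
    "Multi-allelic.*'G'")
  expect_equal(tbl$minor, "G")
  expect_equal(tbl$maf, 0.2)
})

test_that("non-single-base and rare records are handled", {
  expect_warning(
    tbl <- read_snp_table(c("chr1\t10\trs4\tAT\tA\t.\t.\tAF=0.2",
                            "chr1\t20\trs5\tG\tC\t.\t.\tAF=0.005"),
                          dialect = "vcf_min"),
    "rs4")
  expect_equal(tbl$rsid, "rs5")     # indel skipped, rare record kept
  expect_false(tbl$common)          # ... but flagged not common
})

test_that("VCF format errors carry line numbers and class", {
  expect_error(read_snp_table("chr1\t10\trs1", dialect = "vcf_min"),
               "line 1.*fewer than 5", class = "rsnpscan_format_error")
  expect_error(
    read_snp_table("chr1\t10\trs1\tA\tC\t.\t.\tDP=3", dialect = "vcf_min"),
    "AF", class = "rsnpscan_format_error")
})

test_that("TSV dialect accepts canonical and aliased headers", {
  canon <- c("rsid\tchrom\tpos\tmajor\tminor\tmaf",
             "rs9\tchr2\t500\tA\tG\t0.25")
  alias <- c("id\tchr\tpos\tmajor_allele\tminor_allele\tfreq",
             "rs9\tchr2\t500\tA\tG\t0.25")
  expect_equal(read_snp_table(canon, dialect = "tsv"),
               read_snp_table(alias, dialect = "tsv"))
  expect_error(
    read_snp_table(c("rsid\tchrom\tpos", "a\tb\t1"), dialect = "tsv"),
    "missing column", class = "rsnpscan_format_error")
})

test_that("SNP table writes and reads back through the TSV dialect", {
  tbl <- read_snp_table("chr1\t150\trs1\tG\tA\t.\t.\tAF=0.12",
                        dialect = "vcf_min")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snp_table(tbl, path)
  expect_equal(read_snp_table(path, dialect = "tsv"), tbl)
})

# BED accessibility tracks ------------------------------------------------

test_that("read_bed merges overlapping and bookended intervals", {
  trk <- read_bed(c("chr1\t100\t200", "chr1\t150\t250", "chr1\t250\t300",
                    "chr1\t400\t450", "chr2\t0\t10"), cell_line = "Hcm")
  expect_equal(trk$cell_line, rep("Hcm", 3))
  expect_equal(trk$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(trk$start, c(100L, 400L, 0L))
  expect_equal(trk$end, c(300L, 450L, 10L))
})

test_that("read_bed skips comments and errors with line numbers", {
  expect_equal(nrow(read_bed(c("# c", "track name=x"))), 0L)
  expect_error(read_bed("chr1\t100"), "line 1.*fewer than 3",
               class = "rsnpscan_format_error")
  expect_error(read_bed(c("chr1\t0\t10", "chr1\t200\t100")),
               "line 2.*not less than", class = "rsnpscan_format_error")
  expect_error(read_bed("chr1\tx\ty"), "non-numeric",
               class = "rsnpscan_format_error")
})

test_that("is_accessible uses half-open interval semantics", {
  trk <- read_bed("chr1\t100\t200")
  expect_equal(is_accessible(trk, "chr1", c(100, 101, 200, 201)),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_false(is_accessible(trk, "chr2", 150))
})

test_that("merge_intervals is idempotent and never grows coverage", {
  iv <- tibble::tibble(chrom = "c", start = c(5L, 0L, 20L),
                       end = c(15L, 10L, 30L))
  m1 <- merge_intervals(iv)
  expect_equal(merge_intervals(m1), m1)
  expect_lte(sum(m1$end - m1$start), sum(iv$end - iv$start))
})

# Calls and evidence tables ----------------------------------------------

test_that("calls TSV round-trips through the report layout", {
  calls <- fd_rsnp_calls()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls_tsv(calls, path)
  header <- readr::read_lines(path, n_max = 1)
  expect_equal(header,
               paste("Gene", "rSNP", "CellLine", "TF", "RBS_M", "RBSm",
                     "AffinityImpactPct", "HR", "HWF", "FIF", "Category",
                     sep = "\t"))
  back <- read_calls_tsv(path)
  expect_equal(back$rsid, calls$rsid)
  expect_equal(back$fif, calls$fif)           # fixture values are 2-dp
  expect_equal(as.character(back$category), as.character(calls$category))
  expect_error(read_calls_tsv(withr::local_tempfile(lines = "Gene\tFIF")),
               "missing column", class = "rsnpscan_format_error")
})

test_that("evidence TSV reads ND and empty cells as NA", {
  path <- withr::local_tempfile(lines = c(
    "rsid\tgwava_label\tdeepsea_eqtl_prob\tgtex_m_value",
    "rs1\tdeleterious\tND\t",
    "rs2\tneutral\t0.7\t0.95"))
  ev <- read_evidence_tsv(path)
  expect_true(is.na(ev$deepsea_eqtl_prob[1]))
  expect_true(is.na(ev$gtex_m_value[1]))
  expect_type(ev$deepsea_eqtl_prob, "double")
  expect_error(read_evidence_tsv(withr::local_tempfile(lines = "gene\tx")),
               "rsid", class = "rsnpscan_format_error")
})
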