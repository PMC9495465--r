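# Synthetic motif set -----------------------------------------------------

test_that("synthetic PFMs have the documented two-tier profile", {
  pfms <- synthetic_pfms(seed = 3)
  expect_length(pfms, 3)
  for (p in pfms) {
    expect_equal(motif_width(p), 16L)
    core <- attr(p, "core_column")
    expect_equal(core, 8L)
    expect_equal(sort(unique(as.vector(p$counts[, core]))), c(1, 997))
    expect_equal(sort(unique(as.vector(p$counts[, -core]))), c(3, 90))
  }
  # consensi are pairwise dissimilar (Hamming >= 4)
  cons <- vapply(pfms, consensus, character(1))
  for (i in 1:2) for (j in (i + 1):3) {
    d <- sum(strsplit(cons[i], "")[[1]] != strsplit(cons[j], "")[[1]])
    expect_gte(d, 4)
  }
})

test_that("background_from_gc returns valid probabilities", {
  bg <- background_from_gc(0.41)
  expect_equal(sum(bg), 1)
  expect_equal(bg[["C"]], bg[["G"]])
  expect_equal(bg[["A"]], bg[["T"]])
  expect_equal(bg[["C"]] + bg[["G"]], 0.41)
})

# Fixture generation ------------------------------------------------------

test_that("the same seed reproduces a fixture byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_fixture(n_genes = 2, seed = 99, out_dir = d1)
  generate_fixture(n_genes = 2, seed = 99, out_dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 6)
  for (f in files) {
    expect_identical(readr::read_file(file.path(d1, f)),
                     readr::read_file(file.path(d2, f)))
  }
  # a different seed changes the genome
  d3 <- withr::local_tempdir()
  generate_fixture(n_genes = 2, seed = 100, out_dir = d3)
  expect_false(identical(
    readr::read_file(file.path(d1, "synthetic_genome.fa")),
    readr::read_file(file.path(d3, "synthetic_genome.fa"))))
})

test_that("effect mix is honoured exactly by largest-remainder rounding", {
  fx <- generate_fixture(n_genes = 4, seed = 12)
  per_gene <- table(fx$truth$gene, fx$truth$effect)
  for (g in rownames(per_gene)) {
    expect_equal(per_gene[g, "destroyer"], 2)   # floor(1.5) + remainder
    expect_equal(per_gene[g, "creator"], 1)
    expect_equal(per_gene[g, "neutral"], 2)
  }
  expect_equal(nrow(fx$snps), 20L)
  expect_true(all(fx$snps$common))
})

test_that("planted truth is consistent with the planted sequences", {
  fx <- generate_fixture(n_genes = 4, seed = 12)
  pwms <- lapply(fx$pfms, pfm_to_pwm, background = fx$background)
  names(pwms) <- vapply(fx$pfms, `[[`, character(1), "tf_name")
  for (gi in seq_len(nrow(fx$genes))) {
    g <- fx$genes[gi, ]
    pp <- suppressMessages(build_pseudopromoter(g, fx$genome, fx$snps))
    tr <- fx$truth[fx$truth$gene == g$gene, ]
    for (i in seq_len(nrow(tr))) {
      row <- tr[i, ]
      snp <- pp$snps[pp$snps$rsid == row$rsid, ]
      if (row$effect == "neutral") {
        # motif-free guarantee: no overlapping window of any PWM reaches
        # the floor for either allele
        seq_minor <- apply_minor_allele(pp, row$rsid)
        for (pw in pwms) {
          hit <- scan_snp(pw, pp$sequence, seq_minor, snp$offset)
          if (nrow(hit)) {
            expect_lt(max(hit$rbs_major, hit$rbs_minor), 0.80)
          }
        }
      } else {
        pw <- pwms[[row$tf]]
        site <- substr(pp$sequence, row$site_offset + 1,
                       row$site_offset + motif_width(pw))
        if (row$effect == "destroyer") {
          # major-allele site is the exact consensus
          expect_equal(site, consensus(fx$pfms[[match(row$tf, names(pwms))]]))
          expect_equal(relative_score(pw, site), 1)
        } else {
          # creator: major site is a near-miss, minor allele restores it
          expect_lt(relative_score(pw, site), 0.90)
          seq_minor <- apply_minor_allele(pp, row$rsid)
          site_minor <- substr(seq_minor, row$site_offset + 1,
                               row$site_offset + motif_width(pw))
          expect_equal(relative_score(pw, site_minor), 1)
        }
      }
    }
  }
})

test_that("truth accessibility matches the merged peaks", {
  fx <- generate_fixture(n_genes = 6, seed = 8)
  i <- match(fx$truth$rsid, fx$snps$rsid)
  trk <- fx$tracks[fx$tracks$cell_line == "Hcm", ]
  expect_equal(fx$truth$accessible,
               is_accessible(trk, fx$snps$chrom[i], fx$snps$pos[i]))
  # both strands are exercised
  expect_setequal(unique(fx$genes$strand), c("+", "-"))
})

test_that("an empty fixture is still well formed", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(n_genes = 0, seed = 1, out_dir = d)
  expect_equal(nrow(fx$genes), 0L)
  expect_equal(nrow(fx$snps), 0L)
  expect_equal(nrow(fx$truth), 0L)
  expect_true(file.exists(file.path(d, "manifest.yaml")))
  expect_true(file.exists(file.path(d, "synthetic_snps.tsv")))
})

test_that("fixture files parse back through the package readers", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(n_genes = 2, seed = 21, out_dir = d)
  snps <- read_snp_table(file.path(d, "synthetic_snps.tsv"), dialect = "tsv")
  expect_equal(snps$rsid, fx$snps$rsid)
  expect_equal(snps$maf, fx$snps$maf)
  pfms <- read_jaspar_pfm(file.path(d, "synthetic_pfms.jaspar"))
  expect_equal(vapply(pfms, consensus, character(1)),
               vapply(fx$pfms, consensus, character(1)))
  genome <- Biostrings::readDNAStringSet(file.path(d, "synthetic_genome.fa"))
  expect_equal(as.character(genome[[1]]), unname(fx$genome[1]))
  trk <- read_bed(file.path(d, "synthetic_dnase_Hcm.bed"), cell_line = "Hcm")
  expect_equal(trk$start, fx$tracks$start[fx$tracks$cell_line == "Hcm"])
  manifest <- read_run_config(file.path(d, "manifest.yaml"))
  expect_equal(manifest$seed, 21)
  expect_equal(manifest$gc, 0.41)
})

test_that("largest-remainder splits are exact", {
  expect_equal(
    unname(rsnpscan:::largest_remainder(
      c(destroyer = 0.3, creator = 0.3, neutral = 0.4), 5)),
    c(2L, 1L, 2L))
  expect_equal(
    unname(rsnpscan:::largest_remainder(
      c(a = 1 / 3, b = 1 / 3, c = 1 / 3), 10)),
    c(4L, 3L, 3L))
  expect_error(generate_fixture(n_genes = 1, seed = 1,
                                effect_mix = c(0.6, 0.2, 0.2)))
})

test_that("packaged study tables have the published shape", {
  panel <- fd_gene_panel()
  expect_equal(nrow(panel), 14L)
  expect_equal(sum(panel$n_common_snps), 110L)
  calls <- fd_rsnp_calls()
  expect_equal(nrow(calls), 27L)
  expect_equal(sum(calls$sign_inconsistent), 2L)
  expect_true(all(calls$rsid[calls$sign_inconsistent] == "rs4987025"))
  ev <- fd_evidence()
  expect_equal(nrow(ev), 12L)
  expect_setequal(unique(ev$rsid), unique(calls$rsid))
})
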