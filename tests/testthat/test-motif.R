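# PWM transform ----------------------------------------------------------

test_that("pfm_to_pwm matches the closed-form log-odds weight", {
  # Column (10,0,0,0), pseudocount 0.8, uniform background:
  #   w_A = log2(((10 + 0.8*0.25) / 10.8) / 0.25)
  p <- pfm("X", "X", matrix(c(10, 0, 0, 0), 4, 1))
  pw <- pfm_to_pwm(p)
  expect_equal(unname(pw$weights["A", 1]), log2((10.2 / 10.8) / 0.25))
  expect_equal(unname(pw$weights["C", 1]), log2((0.2 / 10.8) / 0.25))
  expect_equal(pw$score_max, max(pw$weights[, 1]))
  expect_equal(pw$score_min, min(pw$weights[, 1]))
})

test_that("background shifts weights; invalid backgrounds are rejected", {
  p <- toy_pfm()
  at_rich <- background_from_gc(0.2)
  pw <- pfm_to_pwm(p, background = at_rich)
  # consensus base A at column 1 is less surprising under an AT-rich
  # background, so its weight is lower than under the uniform background
  expect_lt(pw$weights["A", 1], pfm_to_pwm(p)$weights["A", 1])
  expect_error(pfm_to_pwm(p, background = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(pfm_to_pwm(p, background = c(1, 0, 0, 0)), "positive")
  expect_error(pfm_to_pwm(p, pseudocount = 0))
})

test_that("relative score is 1 at consensus, 0 at the worst window", {
  pw <- toy_pwm()
  expect_equal(relative_score(pw, "ACGT"), 1)
  worst <- paste(c("A", "C", "G", "T")[apply(pw$weights, 2, which.min)],
                 collapse = "")
  expect_equal(relative_score(pw, worst), 0)
  mid <- relative_score(pw, "ACGA")
  expect_gt(mid, 0); expect_lt(mid, 1)
})

test_that("relative score handles N and wrong lengths", {
  pw <- toy_pwm()
  expect_true(is.na(relative_score(pw, "ACNT")))
  expect_error(relative_score(pw, "ACGTA"), "length 5.*width 4")
})

test_that("scoring a reverse-complemented window with pwm_revcomp agrees", {
  set.seed(11)
  pw <- toy_pwm()
  rc <- pwm_revcomp(pw)
  for (i in 1:25) {
    win <- random_dna(4)
    expect_equal(relative_score(pw, win), relative_score(rc, revcomp(win)))
  }
  expect_equal(rc$score_min, pw$score_min)
  expect_equal(rc$score_max, pw$score_max)
  # involution
  expect_equal(pwm_revcomp(rc)$weights, pw$weights)
})

# scan_snp ----------------------------------------------------------------

test_that("scan_snp finds a planted consensus site on either strand", {
  pw <- toy_pwm()
  seq_major <- "TTTTTACGTTTTTT"       # consensus ACGT at offset 5
  seq_minor <- "TTTTTACTTTTTTT"       # SNP at offset 7 breaks it
  hit <- scan_snp(pw, seq_major, seq_minor, 7L)
  expect_equal(hit$offset, 5L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$rbs_major, 1)
  expect_lt(hit$rbs_minor, 1)

  # same site on the minus strand: plant revcomp(ACGT) = ACGT is its own
  # revcomp for this motif? No - use a non-palindromic motif instead
  counts <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T")))
  counts["A", 1] <- 97; counts["A", 2] <- 97
  counts["C", 3] <- 97; counts["G", 4] <- 97
  pw2 <- pfm_to_pwm(pfm("Q", "Q", counts))       # consensus AACG
  seqM <- "TTTTTCGTTTTTTT"                       # revcomp(AACG) = CGTT at 5
  seqm <- "TTTTTCGATTTTTT"
  hit2 <- scan_snp(pw2, seqM, seqm, 7L)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$offset, 5L)
  expect_equal(hit2$rbs_major, 1)
})

test_that("a site created by the minor allele is found", {
  pw <- toy_pwm()
  seq_major <- "TTTTTACTTTTTTT"
  seq_minor <- "TTTTTACGTTTTTT"       # minor allele completes ACGT
  hit <- scan_snp(pw, seq_major, seq_minor, 7L)
  expect_equal(hit$offset, 5L)
  expect_equal(hit$rbs_minor, 1)
  expect_lt(hit$rbs_major, hit$rbs_minor)
})

test_that("scan_snp equals the brute-force oracle on random 50-mers", {
  set.seed(20)
  pw <- toy_pwm()
  for (i in 1:60) {
    s_major <- random_dna(50)
    off <- sample.int(50, 1) - 1L
    major <- substr(s_major, off + 1, off + 1)
    minor <- sample(setdiff(c("A", "C", "G", "T"), major), 1)
    s_minor <- s_major
    substr(s_minor, off + 1, off + 1) <- minor
    got <- scan_snp(pw, s_major, s_minor, off)
    want <- brute_scan_snp(pw, s_major, s_minor, off)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$rbs_major, want$rbs_major)
    expect_equal(got$rbs_minor, want$rbs_minor)
  }
})

test_that("scan_snp matches an exhaustive dimer oracle", {
  # Width-2 motif: every window overlapping the SNP can be enumerated by
  # hand for all 4^3 three-base neighbourhoods.
  counts <- matrix(1, 4, 2, dimnames = list(c("A", "C", "G", "T")))
  counts["C", 1] <- 50; counts["G", 2] <- 50
  pw <- pfm_to_pwm(pfm("D", "D", counts))
  bases <- c("A", "C", "G", "T")
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    s_major <- paste0(b1, b2, b3)
    minor <- setdiff(bases, b2)[1]
    s_minor <- paste0(b1, minor, b3)
    got <- scan_snp(pw, s_major, s_minor, 1L)
    want <- brute_scan_snp(pw, s_major, s_minor, 1L)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("ties break to smaller offset and + strand", {
  pw <- palindromic_pwm()
  # palindrome-symmetric weights: both strands score equally everywhere
  hit <- scan_snp(pw, "TTACGTTT", "TTACGATT", 5L)
  expect_equal(hit$strand, "+")
  # two equal consensus windows overlapping the SNP: smaller offset wins
  pw1 <- pfm_to_pwm(pfm("H", "H", {
    m <- matrix(1, 4, 2, dimnames = list(c("A", "C", "G", "T")))
    m["A", 1] <- 50; m["A", 2] <- 50; m
  }))
  hit2 <- scan_snp(pw1, "AAAA", "ACAA", 1L)   # windows at 0 and 1 both hold AA
  expect_equal(hit2$offset, 0L)
})

test_that("scan_snp edge behaviour: bounds, N windows, short sequences", {
  pw <- toy_pwm()
  expect_error(scan_snp(pw, "ACGT", "ACGT", 4L), "out of sequence")
  expect_error(scan_snp(pw, "ACGTA", "ACGT", 1L), "equal length")
  expect_equal(nrow(scan_snp(pw, "ACG", "ACT", 1L)), 0L)   # shorter than motif
  expect_equal(nrow(scan_snp(pw, "NNNNNN", "NNNNTN", 4L)), 0L)
  # SNP at position 0: only the window starting at 0 is a candidate
  hit <- scan_snp(pw, "ACGTTT", "CCGTTT", 0L)
  expect_equal(hit$offset, 0L)
})

# Homotypic site counting -------------------------------------------------

test_that("count_homotypic_sites counts distinct sites above the floor", {
  pw <- toy_pwm()
  none <- paste(rep("T", 40), collapse = "")
  expect_equal(count_homotypic_sites(pw, none), 0L)
  one <- paste0("TTTTTACGT", paste(rep("T", 20), collapse = ""))
  expect_equal(count_homotypic_sites(pw, one), 1L)
  two <- paste0("TTTTTACGTTTTTTTTTTACGTTTTT")
  expect_equal(count_homotypic_sites(pw, two), 2L)
})

test_that("overlapping tandem matches are suppressed to one site", {
  # Poly-A motif: AAAA at every offset of AAAAAA; greedy NMS keeps sites
  # at non-overlapping offsets only.
  m <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T")))
  m["A", ] <- 50
  pw <- pfm_to_pwm(pfm("P", "P", m))
  expect_equal(count_homotypic_sites(pw, "AAAAAA"), 1L)
  # two plus-strand AAAA sites plus the minus-strand site on TTTT
  expect_equal(count_homotypic_sites(pw, "AAAATTTTAAAA"), 3L)
  expect_equal(count_homotypic_sites(pw, "AAAACCCCAAAA"), 2L)
})

test_that("site counts are monotone in the threshold", {
  set.seed(33)
  pw <- toy_pwm()
  s <- random_dna(300)
  counts <- vapply(c(0.5, 0.7, 0.9, 1.0), function(th) {
    count_homotypic_sites(pw, s, rbs_threshold = th)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(count_homotypic_sites(pw, s, rbs_threshold = 0))
})
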