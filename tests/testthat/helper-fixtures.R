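# Shared toy objects for the test suite.

# A sharp width-4 motif with consensus ACGT: strong counts on the consensus
# base, ones elsewhere.
toy_pfm <- function(id = "MX0001", tf = "TOY") {
  counts <- matrix(1, nrow = 4, ncol = 4,
                   dimnames = list(c("A", "C", "G", "T")))
  counts[cbind(1:4, 1:4)] <- 97
  pfm(id, tf, counts)
}

toy_pwm <- function(...) pfm_to_pwm(toy_pfm(), ...)

# A strictly palindromic motif (consensus ACGT == its reverse complement)
# whose counts are symmetric under reverse complement, so every window
# scores identically on both strands.
palindromic_pwm <- function() {
  counts <- matrix(1, nrow = 4, ncol = 4,
                   dimnames = list(c("A", "C", "G", "T")))
  counts[cbind(1:4, 1:4)] <- 97
  pfm_to_pwm(pfm("PAL", "PAL", counts))
}

# Random DNA of length n (uses the current RNG stream).
random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Brute-force reference for scan_snp(): enumerate every window overlapping
# the SNP on both strands with relative_score(), pick the window maximising
# max(rbs_major, rbs_minor), ties to smaller offset then "+" strand.
brute_scan_snp <- function(pwm, seq_major, seq_minor, snp_offset) {
  w <- motif_width(pwm)
  n <- nchar(seq_major)
  o_min <- max(0L, snp_offset - w + 1L)
  o_max <- min(n - w, snp_offset)
  if (o_max < o_min) {
    return(tibble::tibble(offset = integer(), strand = character(),
                          rbs_major = numeric(), rbs_minor = numeric()))
  }
  rows <- list()
  for (o in o_min:o_max) {
    for (s in c("+", "-")) {
      win_M <- substr(seq_major, o + 1L, o + w)
      win_m <- substr(seq_minor, o + 1L, o + w)
      if (s == "-") {
        win_M <- revcomp(win_M)
        win_m <- revcomp(win_m)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        offset = o, strand = s,
        rbs_major = relative_score(pwm, win_M),
        rbs_minor = relative_score(pwm, win_m))
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out[!is.na(out$rbs_major) & !is.na(out$rbs_minor), , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  best <- pmax(out$rbs_major, out$rbs_minor)
  out[order(-best, out$offset, out$strand)[1], , drop = FALSE]
}
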