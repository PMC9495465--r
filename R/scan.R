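#' Score both alleles of a SNP at its best-binding window
#'
#' Scans every motif window overlapping the SNP on both strands (minus-strand
#' windows are scored on their reverse complement) for the major-allele and
#' the minor-allele sequence. The reported pair of relative binding scores
#' (RBS) comes from the single window and strand maximising
#' `max(RBS_major, RBS_minor)`, so both alleles are always compared at the
#' same site; a site created by the minor allele is still found because the
#' window is chosen over both alleles. Ties are broken by smaller offset,
#' then `+` strand before `-`.
#'
#' @param pwm A `pwm` from [pfm_to_pwm()].
#' @param seq_major,seq_minor Equal-length promoter sequences differing only
#'   at `snp_offset`.
#' @param snp_offset 0-based position of the SNP in the sequences. Near a
#'   sequence end the candidate set is truncated to in-bounds windows.
#' @return A one-row tibble with `offset` (0-based window start), `strand`,
#'   `rbs_major`, `rbs_minor`; zero rows if no valid window overlaps the SNP
#'   (sequence shorter than the motif, or all windows contain `N`).
#' @export
scan_snp <- function(pwm, seq_major, seq_minor, snp_offset) {
  stopifnot(is_pwm(pwm))
  n <- nchar(seq_major)
  if (nchar(seq_minor) != n) {
    abort("major and minor sequences must have equal length")
  }
  if (snp_offset < 0L || snp_offset >= n) {
    abort("snp_offset out of sequence bounds")
  }
  w <- ncol(pwm$weights)
  empty <- tibble(offset = integer(), strand = character(),
                  rbs_major = numeric(), rbs_minor = numeric())
  o_min <- max(0L, snp_offset - w + 1L)
  o_max <- min(n - w, snp_offset)
  if (o_max < o_min) return(empty)

  region <- function(seq) substr(seq, o_min + 1L, o_max + w)
  maj <- score_windows(pwm, region(seq_major))
  mnr <- score_windows(pwm, region(seq_minor))
  both <- dplyr::inner_join(maj, mnr, by = c("offset", "strand"),
                            suffix = c("_major", "_minor"))
  if (nrow(both) == 0L) return(empty)
  both$offset <- both$offset + o_min
  best <- pmax(both$rbs_major, both$rbs_minor)
  ord <- order(-best, both$offset, both$strand)  # "+" < "-" in C locale
  both <- both[ord[1], , drop = FALSE]
  dplyr::select(both, "offset", "strand", "rbs_major", "rbs_minor")
}

#' Count homotypic binding sites in a promoter
#'
#' Homotypic redundancy (HR): the number of distinct sites for one
#' transcription factor in the major-allele promoter with relative binding
#' score at or above a threshold, on either strand. Candidate windows are
#' accepted greedily, best score first (ties: smaller offset, `+` before
#' `-`), and any window overlapping an accepted site is suppressed, so
#' tandem overlapping matches count once.
#'
#' @param pwm A `pwm`.
#' @param seq Promoter sequence (major-allele).
#' @param rbs_threshold Site-calling floor in `(0, 1]` (default 0.80, the
#'   reporting floor of the scoring chain).
#' @return Integer site count (possibly 0).
#' @export
count_homotypic_sites <- function(pwm, seq, rbs_threshold = 0.80) {
  stopifnot(is_pwm(pwm), rbs_threshold > 0, rbs_threshold <= 1)
  w <- ncol(pwm$weights)
  hits <- score_windows(pwm, seq)
  hits <- hits[hits$rbs >= rbs_threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(0L)
  hits <- hits[order(-hits$rbs, hits$offset, hits$strand), , drop = FALSE]
  kept_start <- integer(0)
  for (i in seq_len(nrow(hits))) {
    o <- hits$offset[i]
    if (!any(o < kept_start + w & kept_start < o + w)) {
      kept_start <- c(kept_start, o)
    }
  }
  length(kept_start)
}
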