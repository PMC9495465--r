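#' The rSNP scoring chain: affinity impact, HWF, FIF, category
#'
#' Four small, exact functions make up the quantitative chain applied to each
#' (SNP, transcription factor) pair after motif scanning:
#'
#' * `affinity_impact()` — signed percent change in relative binding score
#'   from major to minor allele, `100 * (RBSm - RBS_M) / RBS_M`. Negative
#'   values mean the minor allele loses affinity.
#' * `hwf_of()` — the homotypic redundancy weight factor `1 / HR`, which
#'   discounts the loss of one among `HR` redundant sites of the same factor.
#' * `fif_of()` — the functional impact factor,
#'   `FIF = affinity impact × HWF`.
#' * `categorize()` — the reporting rule: `|FIF|` at or below the threshold
#'   (default 10) is `below_threshold`; `FIF` below the negative gate is
#'   `decreased_affinity`; `FIF` above the positive gate suggests the
#'   creation of a new binding site (`new_tfbs_suggested`). With
#'   `strong_site_as_increased = TRUE`, a positive call whose two alleles
#'   both already reach `rbs_floor` is relabelled `increased_affinity`
#'   (strengthening of an existing site) instead.
#'
#' All four are vectorised.
#'
#' @param rbs_major,rbs_minor Relative binding scores in `[0, 1]`;
#'   `rbs_major` must be positive for `affinity_impact()`.
#' @param hr Homotypic redundancy, integer `>= 1`.
#' @param affinity_impact_pct Signed percent affinity impact.
#' @param fif Functional impact factor.
#' @param fif_threshold Reporting gate on `|FIF|` (default 10).
#' @param rbs_floor Site-calling floor (default 0.80).
#' @param strong_site_as_increased Alternative labelling rule for positive
#'   calls (default `FALSE`; see above).
#' @return `affinity_impact()`, `hwf_of()`, `fif_of()`: numeric vectors.
#'   `categorize()`: a factor with levels `decreased_affinity`,
#'   `increased_affinity`, `new_tfbs_suggested`, `below_threshold`.
#' @examples
#' affinity_impact(0.80, 0.61)   # -23.75
#' fif_of(-23.68, 2)             # -11.84
#' categorize(fif_of(-23.68, 2), 0.80, 0.61)
#' @name scoring-chain
NULL

#' @rdname scoring-chain
#' @export
affinity_impact <- function(rbs_major, rbs_minor) {
  if (any(rbs_major <= 0)) {
    abort("affinity impact is undefined for rbs_major = 0")
  }
  100 * (rbs_minor - rbs_major) / rbs_major
}

#' @rdname scoring-chain
#' @export
hwf_of <- function(hr) {
  if (any(hr < 1)) abort("homotypic redundancy must be >= 1")
  1 / hr
}

#' @rdname scoring-chain
#' @export
fif_of <- function(affinity_impact_pct, hr) {
  affinity_impact_pct * hwf_of(hr)
}

#' @rdname scoring-chain
#' @export
categorize <- function(fif, rbs_major, rbs_minor, fif_threshold = 10,
                       rbs_floor = 0.80, strong_site_as_increased = FALSE) {
  n <- max(length(fif), length(rbs_major), length(rbs_minor))
  fif <- rep_len(fif, n)
  rbs_major <- rep_len(rbs_major, n)
  rbs_minor <- rep_len(rbs_minor, n)
  out <- rep("below_threshold", n)
  out[fif < -fif_threshold] <- "decreased_affinity"
  pos <- fif > fif_threshold
  out[pos] <- "new_tfbs_suggested"
  if (strong_site_as_increased) {
    out[pos & rbs_major >= rbs_floor & rbs_minor >= rbs_floor] <-
      "increased_affinity"
  }
  factor(out, levels = c("decreased_affinity", "increased_affinity",
                         "new_tfbs_suggested", "below_threshold"))
}

#' Call regulatory SNPs across promoters, motifs and cell lines
#'
#' The full prediction pass. For every (promoter, SNP, cell line) where the
#' SNP falls in open chromatin of that cell line, and for every PWM:
#'
#' 1. [scan_snp()] scores both alleles at the best window overlapping the
#'    SNP; pairs with `max(RBS_M, RBSm)` below `rbs_floor` are dropped.
#' 2. Homotypic redundancy is counted on the major-allele promoter with
#'    [count_homotypic_sites()] (floored at 1: the SNP's own site counts).
#' 3. Affinity impact, HWF and FIF are computed; pairs with `|FIF|` at or
#'    below `fif_threshold` are dropped; survivors are categorised.
#'
#' @param promoters A `pseudo_promoter` or list of them.
#' @param pwms A `pwm`/[pfm] or list of them (PFMs are converted with the
#'   given `pseudocount` and `background`).
#' @param tracks Accessibility tibble with columns `cell_line`, `chrom`,
#'   `start`, `end` (e.g. row-bound [read_bed()] outputs).
#' @param rbs_floor Relative-binding-score reporting floor (default 0.80).
#' @param fif_threshold Reporting gate on `|FIF|` (default 10).
#' @param pseudocount,background Passed to [pfm_to_pwm()] for any PFM input.
#' @param hr_threshold Site floor used for HR counting (defaults to
#'   `rbs_floor`).
#' @param strong_site_as_increased Passed to [categorize()].
#' @param common_only Score only SNPs flagged common (MAF > 1%); default
#'   `TRUE`.
#' @return A tibble of class `rsnp_calls`, one row per surviving
#'   (gene, SNP, cell line, TF): columns `gene`, `rsid`, `cell_line`, `tf`,
#'   `offset`, `strand`, `rbs_major`, `rbs_minor`, `affinity_impact_pct`,
#'   `hr`, `hwf`, `fif`, `category`, ordered by gene, rsid, cell line, TF.
#'   Zero rows is a valid result.
#' @export
call_rsnps <- function(promoters, pwms, tracks,
                       rbs_floor = 0.80, fif_threshold = 10,
                       pseudocount = 0.8, background = rep(0.25, 4),
                       hr_threshold = rbs_floor,
                       strong_site_as_increased = FALSE,
                       common_only = TRUE) {
  if (inherits(promoters, "pseudo_promoter")) promoters <- list(promoters)
  if (is_pwm(pwms) || is_pfm(pwms)) pwms <- list(pwms)
  pwms <- lapply(pwms, function(p) {
    if (is_pfm(p)) pfm_to_pwm(p, pseudocount = pseudocount,
                              background = background) else p
  })
  stopifnot(all(vapply(pwms, is_pwm, logical(1))))
  cell_lines <- unique(tracks$cell_line)

  rows <- list()
  for (pp in promoters) {
    snps <- pp$snps
    if (common_only && nrow(snps) > 0L) {
      snps <- snps[snps$common, , drop = FALSE]
    }
    if (nrow(snps) == 0L) next
    hr_cache <- rep(NA_integer_, length(pwms))
    for (cl in cell_lines) {
      trk <- tracks[tracks$cell_line == cl, , drop = FALSE]
      acc <- is_accessible(trk, pp$chrom, snps$pos)
      for (si in which(acc)) {
        seq_minor <- apply_minor_allele(pp, snps$rsid[si])
        for (mi in seq_along(pwms)) {
          hit <- scan_snp(pwms[[mi]], pp$sequence, seq_minor, snps$offset[si])
          if (nrow(hit) == 0L) next
          if (max(hit$rbs_major, hit$rbs_minor) < rbs_floor) next
          if (hit$rbs_major <= 0) next
          if (is.na(hr_cache[mi])) {
            hr_cache[mi] <- count_homotypic_sites(pwms[[mi]], pp$sequence,
                                                  rbs_threshold = hr_threshold)
          }
          hr <- max(1L, hr_cache[mi])
          impact <- affinity_impact(hit$rbs_major, hit$rbs_minor)
          fif <- fif_of(impact, hr)
          if (abs(fif) <= fif_threshold) next
          rows[[length(rows) + 1L]] <- tibble(
            gene = pp$gene, rsid = snps$rsid[si], cell_line = cl,
            tf = pwms[[mi]]$tf_name,
            offset = hit$offset, strand = hit$strand,
            rbs_major = hit$rbs_major, rbs_minor = hit$rbs_minor,
            affinity_impact_pct = impact, hr = hr, hwf = 1 / hr, fif = fif,
            category = categorize(fif, hit$rbs_major, hit$rbs_minor,
                                  fif_threshold = fif_threshold,
                                  rbs_floor = rbs_floor,
                                  strong_site_as_increased =
                                    strong_site_as_increased))
        }
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_calls_tbl()
  out <- dplyr::arrange(out, .data$gene, .data$rsid, .data$cell_line, .data$tf)
  new_rsnp_calls(out)
}

empty_calls_tbl <- function() {
  tibble(gene = character(), rsid = character(), cell_line = character(),
         tf = character(), offset = integer(), strand = character(),
         rbs_major = numeric(), rbs_minor = numeric(),
         affinity_impact_pct = numeric(), hr = integer(), hwf = numeric(),
         fif = numeric(),
         category = factor(character(),
                           levels = c("decreased_affinity",
                                      "increased_affinity",
                                      "new_tfbs_suggested",
                                      "below_threshold")))
}

new_rsnp_calls <- function(x) {
  class(x) <- c("rsnp_calls", class(tibble()))
  x
}
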