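#' Transform a PFM into a log-odds PWM
#'
#' Converts base counts into log2-odds weights against a background
#' distribution, with a pseudocount split across bases in proportion to the
#' background:
#'
#' \deqn{w_{b,j} = \log_2 \frac{(n_{b,j} + p\,q_b) / (N_j + p)}{q_b}}
#'
#' where \eqn{n_{b,j}} is the count of base \eqn{b} at column \eqn{j},
#' \eqn{N_j} the column total, \eqn{p} the pseudocount and \eqn{q_b} the
#' background probability. The minimum and maximum achievable raw scores
#' (column-wise minima/maxima summed) are stored for min–max normalisation of
#' window scores.
#'
#' @param x A [pfm] object.
#' @param pseudocount Positive pseudocount (default 0.8, the JASPAR
#'   convention).
#' @param background Length-4 probability vector (A, C, G, T), summing to 1.
#'   Default uniform.
#' @return An object of class `pwm`.
#' @examples
#' p <- pfm("MX0001", "TOY", matrix(c(10, 0, 0, 0, 0, 10, 0, 0), nrow = 4))
#' pfm_to_pwm(p)$score_max
#' @export
pfm_to_pwm <- function(x, pseudocount = 0.8, background = rep(0.25, 4)) {
  stopifnot(is_pfm(x), pseudocount > 0, length(background) == 4L)
  background <- as.numeric(background)
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-8) {
    abort("background must be 4 positive probabilities summing to 1")
  }
  counts <- x$counts
  totals <- colSums(counts)
  probs <- sweep(counts + pseudocount * background, 2, totals + pseudocount, "/")
  weights <- log2(probs / background)
  rownames(weights) <- DNA_BASES
  structure(
    list(matrix_id = x$matrix_id, tf_name = x$tf_name,
         weights = weights,
         background = setNames(background, DNA_BASES),
         pseudocount = pseudocount,
         score_min = sum(apply(weights, 2, min)),
         score_max = sum(apply(weights, 2, max))),
    class = "pwm"
  )
}

#' @rdname pfm_to_pwm
#' @export
is_pwm <- function(x) inherits(x, "pwm")

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$matrix_id, " ", x$tf_name,
      "  (width ", ncol(x$weights),
      ", raw score range [", round(x$score_min, 3), ", ",
      round(x$score_max, 3), "])\n", sep = "")
  print(round(x$weights, 3))
  invisible(x)
}

#' Reverse-complement a PWM
#'
#' Scoring a window's reverse complement with `x` equals scoring the window
#' itself with `pwm_revcomp(x)`; this is how minus-strand scanning is
#' implemented. The achievable score range is unchanged.
#'
#' @param x A `pwm`.
#' @return A `pwm` with columns reversed and complementary rows swapped.
#' @export
pwm_revcomp <- function(x) {
  stopifnot(is_pwm(x))
  w <- x$weights[c("T", "G", "C", "A"), rev(seq_len(ncol(x$weights))),
                 drop = FALSE]
  rownames(w) <- DNA_BASES
  x$weights <- w
  x$background <- setNames(x$background[c("T", "G", "C", "A")], DNA_BASES)
  x
}

#' Relative binding score of a single window
#'
#' The raw log-odds score of a window, min–max normalised to `[0, 1]` over
#' the PWM's achievable range: `(raw - score_min) / (score_max - score_min)`.
#' A window equal to the consensus scores exactly 1; the worst possible
#' window scores exactly 0.
#'
#' @param pwm A `pwm`.
#' @param window A string of length `motif_width(pwm)` over A/C/G/T.
#' @return A number in `[0, 1]`; `NA` if the window contains `N`.
#' @export
relative_score <- function(pwm, window) {
  stopifnot(is_pwm(pwm))
  w <- ncol(pwm$weights)
  if (nchar(window) != w) {
    abort(paste0("Window length ", nchar(window), " does not match motif width ",
                 w))
  }
  idx <- encode_seq(window)
  if (anyNA(idx)) return(NA_real_)
  raw <- sum(pwm$weights[cbind(idx, seq_len(w))])
  (raw - pwm$score_min) / (pwm$score_max - pwm$score_min)
}

# Vectorised relative scores of every width-w window of `seq` on both strands.
# Returns a tibble(offset [0-based], strand, rbs); windows containing N are
# dropped.
score_windows <- function(pwm, seq) {
  w <- ncol(pwm$weights)
  n <- nchar(seq)
  if (n < w) {
    return(tibble(offset = integer(), strand = character(), rbs = numeric()))
  }
  idx <- encode_seq(seq)
  n_win <- n - w + 1L
  raw_strand <- function(weights) {
    raw <- numeric(n_win)
    ok <- rep(TRUE, n_win)
    for (j in seq_len(w)) {
      b <- idx[seq_len(n_win) + j - 1L]
      ok <- ok & !is.na(b)
      bj <- b; bj[is.na(bj)] <- 1L
      raw <- raw + weights[cbind(bj, j)]
    }
    raw[!ok] <- NA_real_
    raw
  }
  rng <- pwm$score_max - pwm$score_min
  plus <- (raw_strand(pwm$weights) - pwm$score_min) / rng
  minus <- (raw_strand(pwm_revcomp(pwm)$weights) - pwm$score_min) / rng
  out <- tibble(
    offset = rep(0:(n_win - 1L), 2L),
    strand = rep(c("+", "-"), each = n_win),
    rbs = c(plus, minus))
  out[!is.na(out$rbs), , drop = FALSE]
}
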