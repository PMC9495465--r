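#' Read a BED accessibility track
#'
#' Reads BED3 (optionally BED3+name) open-chromatin intervals for one cell
#' line. Coordinates are 0-based half-open, as in the BED standard. Intervals
#' are sorted and overlapping/adjacent intervals merged on read, so the
#' returned track is normalised: sorted, non-overlapping intervals with
#' `start < end`.
#'
#' @param file Path or character vector of BED lines.
#' @param cell_line Cell-line label attached to every interval (e.g. one of
#'   `"Hcm"`, `"Hcf"`, `"Hac"`, `"Huvec"`, `"TH1"`).
#' @return A tibble with columns `cell_line`, `chrom`, `start`, `end`
#'   (0-based half-open), sorted by chrom then start.
#' @examples
#' read_bed(c("chr1\t100\t200", "chr1\t150\t250"), cell_line = "Hcm")
#' @export
read_bed <- function(file, cell_line = "track") {
  lines <- if (is.character(file) && (length(file) > 1L ||
                                      (!file.exists(file[1]) && grepl("[\n\t]", file[1])))) {
    unlist(strsplit(file, "\n"))
  } else readr::read_lines(file)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(tibble(cell_line = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  f <- strsplit(lines, "[\t ]+")
  bad <- lengths(f) < 3L
  if (any(bad)) {
    abort(paste0("BED line ", which(bad)[1], " has fewer than 3 fields"),
          class = "rsnpscan_format_error")
  }
  tbl <- tibble(
    chrom = vapply(f, `[`, character(1), 1L),
    start = suppressWarnings(as.integer(vapply(f, `[`, character(1), 2L))),
    end = suppressWarnings(as.integer(vapply(f, `[`, character(1), 3L))))
  if (anyNA(tbl$start) || anyNA(tbl$end)) {
    abort(paste0("BED line ", which(is.na(tbl$start) | is.na(tbl$end))[1],
                 ": non-numeric coordinates"),
          class = "rsnpscan_format_error")
  }
  rev_iv <- tbl$start >= tbl$end
  if (any(rev_iv)) {
    abort(paste0("BED line ", which(rev_iv)[1], ": start (",
                 tbl$start[which(rev_iv)[1]], ") is not less than end (",
                 tbl$end[which(rev_iv)[1]], ")"),
          class = "rsnpscan_format_error")
  }
  out <- merge_intervals(tbl)
  out$cell_line <- cell_line
  dplyr::select(out, "cell_line", "chrom", "start", "end")
}

#' Merge overlapping intervals
#'
#' Normalises a set of 0-based half-open intervals: sorts and merges
#' overlapping or bookended intervals per chromosome (via `IRanges::reduce()`).
#' Idempotent; the total covered length never increases.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end` (and
#'   optionally others, which are dropped).
#' @return Tibble with columns `chrom`, `start`, `end`, sorted.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  pieces <- lapply(split(intervals, intervals$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    tibble(chrom = d$chrom[1],
           start = IRanges::start(r) - 1L,
           end = IRanges::end(r))
  })
  out <- dplyr::bind_rows(pieces)
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Test chromatin accessibility at a position
#'
#' Is a 1-based genomic position inside any open-chromatin interval of a
#' track? Interval semantics are 0-based half-open, so 1-based position `p`
#' is accessible iff `start <= p - 1 < end` for some interval on the same
#' chromosome.
#'
#' @param track A normalised track tibble from [read_bed()] (columns `chrom`,
#'   `start`, `end`; a `cell_line` column, if present, is ignored — filter
#'   first for multi-track tibbles).
#' @param chrom Chromosome name (scalar or vector recycled against `pos`).
#' @param pos 1-based position(s).
#' @return Logical vector, one element per position.
#' @examples
#' trk <- read_bed("chr1\t100\t200")
#' is_accessible(trk, "chr1", c(100, 101, 200))  # FALSE TRUE FALSE
#' @export
is_accessible <- function(track, chrom, pos) {
  stopifnot(all(c("chrom", "start", "end") %in% names(track)))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.numeric(pos), n)
  p0 <- pos - 1
  vapply(seq_len(n), function(i) {
    d <- track[track$chrom == chrom[i], , drop = FALSE]
    any(d$start <= p0[i] & p0[i] < d$end)
  }, logical(1))
}
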