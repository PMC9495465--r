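#' Position frequency matrices
#'
#' A `pfm` is a transcription-factor binding model as distributed by motif
#' databases: a 4 x w matrix of non-negative base counts (rows A, C, G, T;
#' one column per motif position), together with a matrix identifier and the
#' factor's name.
#'
#' @param matrix_id Motif identifier (e.g. a JASPAR accession).
#' @param tf_name Transcription-factor name.
#' @param counts Numeric 4 x w matrix of non-negative counts; rows are taken
#'   in A, C, G, T order (rownames, if present, are checked).
#' @return An object of class `pfm`.
#' @examples
#' pfm("MX0001", "TOY", matrix(c(10, 0, 0, 0, 0, 10, 0, 0), nrow = 4))
#' @export
pfm <- function(matrix_id, tf_name, counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != 4L) {
    abort_pfm(matrix_id, "must have exactly 4 rows (A, C, G, T)")
  }
  if (!is.null(rownames(counts)) && !identical(rownames(counts), DNA_BASES)) {
    counts <- counts[DNA_BASES, , drop = FALSE]
  }
  rownames(counts) <- DNA_BASES
  if (anyNA(counts)) abort_pfm(matrix_id, "contains non-numeric counts")
  if (any(counts < 0)) abort_pfm(matrix_id, "contains negative counts")
  if (ncol(counts) < 1L) abort_pfm(matrix_id, "has zero columns")
  if (any(colSums(counts) <= 0)) {
    abort_pfm(matrix_id, "has an all-zero column")
  }
  structure(
    list(matrix_id = as.character(matrix_id),
         tf_name = as.character(tf_name),
         counts = counts),
    class = "pfm"
  )
}

abort_pfm <- function(id, msg) {
  abort(paste0("PFM '", id, "' ", msg), class = "rsnpscan_format_error")
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm> ", x$matrix_id, " ", x$tf_name,
      "  (width ", ncol(x$counts), ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @rdname pfm
#' @param x Object to test or print.
#' @export
is_pfm <- function(x) inherits(x, "pfm")

#' Motif width
#' @param x A [pfm] or `pwm` object.
#' @return Integer motif width (number of columns).
#' @export
motif_width <- function(x) {
  if (is_pfm(x)) return(ncol(x$counts))
  if (is_pwm(x)) return(ncol(x$weights))
  abort("`x` must be a pfm or pwm")
}

#' Consensus sequence of a PFM
#'
#' The highest-count base at each column, ties broken in A, C, G, T order.
#'
#' @param x A [pfm] object.
#' @return A single string of length `motif_width(x)`.
#' @export
consensus <- function(x) {
  stopifnot(is_pfm(x))
  paste(DNA_BASES[apply(x$counts, 2, which.max)], collapse = "")
}

#' Read and write JASPAR-text position frequency matrices
#'
#' The JASPAR flat-text dialect: a header line `>ID NAME` followed by four
#' count rows in A, C, G, T order. Rows may be bracketed (`A [ 10 0 ]`) or
#' bare (`A 10 0`); the writer always emits the bracketed form.
#'
#' @param file Path to a JASPAR-text file, or a character vector of lines
#'   (anything `readr::read_lines()` accepts).
#' @return `read_jaspar_pfm()`: a list of [pfm] objects, in file order (an
#'   empty input yields an empty list). `write_jaspar_pfm()`: the path,
#'   invisibly.
#' @examples
#' pfms <- read_jaspar_pfm(c(">MX0001 TOY", "A [10 0]", "C [0 10]",
#'                           "G [0 0]", "T [0 0]"))
#' consensus(pfms[[1]])
#' @export
read_jaspar_pfm <- function(file) {
  lines <- if (is.character(file) && length(file) > 1L) file
           else if (is.character(file) && !file.exists(file) &&
                    grepl("\n", file)) strsplit(file, "\n")[[1]]
           else readr::read_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  starts <- grep("^>", lines)
  if (length(starts) == 0L || starts[1] != 1L) {
    abort("JASPAR input must start with a '>' header line",
          class = "rsnpscan_format_error")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  purrr::map2(starts, ends, function(s, e) {
    header <- sub("^>\\s*", "", lines[s])
    parts <- strsplit(trimws(header), "\\s+")[[1]]
    id <- parts[1]
    tf <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else id
    body <- lines[(s + 1L):e]
    if (s == e) abort_pfm(id, "has no count rows")
    if (length(body) != 4L) {
      abort_pfm(id, paste0("has ", length(body), " count rows; expected 4"))
    }
    rows <- lapply(seq_along(body), function(i) {
      ln <- trimws(body[i])
      base <- sub("^([ACGTacgt])\\b.*", "\\1", ln)
      if (toupper(base) != DNA_BASES[i] && grepl("^[ACGTacgt]\\b", ln)) {
        abort_pfm(id, paste0("row ", i, " is labelled '", toupper(base),
                             "'; expected '", DNA_BASES[i], "'"))
      }
      ln <- sub("^[ACGTacgt]\\b", "", ln)
      ln <- gsub("\\[|\\]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (length(vals) == 0L || anyNA(vals)) {
        abort_pfm(id, paste0("row ", DNA_BASES[i], " is not numeric"))
      }
      vals
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      abort_pfm(id, paste0("has ragged rows (widths ",
                           paste(widths, collapse = ", "), ")"))
    }
    pfm(id, tf, do.call(rbind, rows))
  })
}

#' @rdname read_jaspar_pfm
#' @param pfms A list of [pfm] objects (or a single one).
#' @param path Output file path.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  if (is_pfm(pfms)) pfms <- list(pfms)
  lines <- unlist(lapply(pfms, function(p) {
    c(paste0(">", p$matrix_id, " ", p$tf_name),
      vapply(seq_len(4L), function(i) {
        paste0(DNA_BASES[i], " [ ",
               paste(format(p$counts[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "),
               " ]")
      }, character(1)))
  }))
  readr::write_lines(lines, path)
  invisible(path)
}
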