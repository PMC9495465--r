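#' Build an allele-aware pseudo-promoter
#'
#' Extracts the proximal promoter — by default the 2000 bases immediately
#' upstream of (and excluding) the transcription start site — and substitutes
#' the major allele of every supplied SNP falling inside it, yielding the
#' "pseudo-promoter" on which all scoring runs. The sequence is stored in
#' promoter orientation (5'→3' on the gene's strand, TSS-proximal end
#' rightmost), so for minus-strand genes the genomic slice
#' `[tss, tss + length)` is reverse-complemented.
#'
#' Genomic coordinates are 1-based on input and converted internally to
#' 0-based half-open: for strand `+` the promoter interval is
#' `[tss - 1 - length, tss - 1)`; for strand `-` it is `[tss, tss + length)`.
#' SNPs outside the interval are excluded (with a message). If the reference
#' base at a SNP position matches neither allele a warning is issued and the
#' major allele is substituted anyway (the pseudo-promoter is defined by the
#' SNP catalogue, not the reference).
#'
#' @param spec A list or one-row data frame with `gene`, `chrom`, `tss`
#'   (1-based), `strand` (`"+"`/`"-"`) and optionally `length` (default 2000).
#' @param genome A named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param snps SNP tibble as returned by [read_snp_table()].
#' @return An object of class `pseudo_promoter`: a list with `gene`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `sequence` and `snps`
#'   (a tibble with local 0-based `offset` into the promoter sequence and
#'   strand-adjusted `major_local`/`minor_local` alleles).
#' @export
build_pseudopromoter <- function(spec, genome, snps = NULL) {
  spec <- as.list(spec)
  len <- as.integer(spec$length %||% 2000L)
  stopifnot(len > 0L)
  strand <- as.character(spec$strand)
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  tss <- as.integer(spec$tss)
  genome <- as_genome(genome)
  if (!spec$chrom %in% names(genome)) {
    abort(paste0("Contig '", spec$chrom, "' not found in genome"))
  }
  contig <- genome[[spec$chrom]]
  if (strand == "+") {
    start <- tss - 1L - len; end <- tss - 1L
  } else {
    start <- tss; end <- tss + len
  }
  if (start < 0L || end > nchar(contig)) {
    abort(paste0("Promoter interval [", start, ",", end,
                 ") out of bounds for contig '", spec$chrom, "' (length ",
                 nchar(contig), ")"))
  }
  seq <- toupper(substr(contig, start + 1L, end))
  if (strand == "-") seq <- revcomp(seq)

  if (is.null(snps)) snps <- empty_snp_tbl()
  snps <- snps[snps$chrom == spec$chrom, , drop = FALSE]
  inside <- snps$pos - 1L >= start & snps$pos - 1L < end
  if (any(!inside)) {
    inform(paste0("Excluding ", sum(!inside), " SNP(s) outside the ",
                  spec$gene, " promoter: ",
                  paste(snps$rsid[!inside], collapse = ", ")))
  }
  snps <- snps[inside, , drop = FALSE]
  g <- snps$pos - 1L - start                      # offset in genomic frame
  offset <- if (strand == "+") g else len - 1L - g
  major_local <- if (strand == "+") snps$major else complement_base(snps$major)
  minor_local <- if (strand == "+") snps$minor else complement_base(snps$minor)

  for (i in seq_along(offset)) {
    ref_base <- substr(seq, offset[i] + 1L, offset[i] + 1L)
    if (!ref_base %in% c(major_local[i], minor_local[i])) {
      warn(paste0("Reference base '", ref_base, "' at ", snps$rsid[i],
                  " matches neither allele (", major_local[i], "/",
                  minor_local[i], "); substituting major allele"))
    }
    substr(seq, offset[i] + 1L, offset[i] + 1L) <- major_local[i]
  }

  snps$offset <- as.integer(offset)
  snps$major_local <- major_local
  snps$minor_local <- minor_local
  snps <- dplyr::arrange(snps, .data$offset)

  structure(
    list(gene = as.character(spec$gene), chrom = as.character(spec$chrom),
         start = start, end = end, strand = strand,
         sequence = seq, snps = snps),
    class = "pseudo_promoter"
  )
}

#' @export
print.pseudo_promoter <- function(x, ...) {
  cat("<pseudo_promoter> ", x$gene, "  ", x$chrom, ":", x$start, "-", x$end,
      " (", x$strand, "), ", nchar(x$sequence), " bp, ",
      nrow(x$snps), " SNP(s)\n", sep = "")
  invisible(x)
}

#' Apply a SNP's minor allele to a pseudo-promoter
#'
#' Returns the promoter sequence with exactly one substitution: the named
#' SNP's minor allele (strand-adjusted) at its local offset. All other SNPs
#' remain at their major allele — the one-SNP-at-a-time haplotype model under
#' which every SNP is scored.
#'
#' @param pp A [build_pseudopromoter()] object.
#' @param rsid SNP identifier; must be present in `pp$snps`.
#' @return A character scalar, same length as `pp$sequence`.
#' @export
apply_minor_allele <- function(pp, rsid) {
  stopifnot(inherits(pp, "pseudo_promoter"))
  i <- match(rsid, pp$snps$rsid)
  if (is.na(i)) {
    abort(paste0("SNP '", rsid, "' is not in the ", pp$gene, " promoter"))
  }
  seq <- pp$sequence
  substr(seq, pp$snps$offset[i] + 1L, pp$snps$offset[i] + 1L) <-
    pp$snps$minor_local[i]
  seq
}

# Accept a named character vector, DNAStringSet, or FASTA path.
# Idempotent: the named-list form it returns passes through unchanged.
as_genome <- function(genome) {
  if (is.list(genome)) {
    ok <- all(vapply(genome, function(x) is.character(x) && length(x) == 1L,
                     logical(1)))
    if (!ok || (length(genome) > 0L && is.null(names(genome)))) {
      abort("genome must be a named character vector, DNAStringSet or FASTA path")
    }
    return(genome)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome),
                       sub("\\s.*$", "", names(genome)))
  }
  if (!is.character(genome) || is.null(names(genome))) {
    abort("genome must be a named character vector, DNAStringSet or FASTA path")
  }
  as.list(genome)
}

#' Write pseudo-promoters as FASTA
#'
#' One record per promoter, headers `>GENE|chrom:start-end|strand`.
#'
#' @param promoters A `pseudo_promoter` or list of them.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  if (inherits(promoters, "pseudo_promoter")) promoters <- list(promoters)
  seqs <- Biostrings::DNAStringSet(vapply(promoters, `[[`, character(1),
                                          "sequence"))
  names(seqs) <- vapply(promoters, function(p) {
    paste0(p$gene, "|", p$chrom, ":", p$start, "-", p$end, "|", p$strand)
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
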