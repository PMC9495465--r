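#' Read a table of biallelic SNPs
#'
#' Reads SNPs from either a minimal VCF subset (`dialect = "vcf_min"`:
#' `CHROM POS ID REF ALT [QUAL FILTER] INFO`, allele frequency taken from an
#' INFO key) or a headed TSV (`dialect = "tsv"` with columns `rsid`, `chrom`,
#' `pos`, `major`, `minor`, `maf`). Positions are 1-based in both dialects.
#'
#' Only biallelic records are kept: a multi-allelic VCF line is reduced to its
#' most frequent ALT allele (a message reports each reduction). When the ALT
#' frequency exceeds 0.5 the alleles are swapped so that `major` is the more
#' frequent allele and `maf` is always in (0, 0.5]. Records whose REF or ALT
#' is not a single A/C/G/T base are skipped with a warning. Records with
#' `maf <= 0.01` are retained but flagged `common = FALSE` (the study analyses
#' common SNPs, MAF > 1%).
#'
#' @param file Path or character vector of lines.
#' @param dialect `"vcf_min"` or `"tsv"`.
#' @param af_key INFO key holding the ALT allele frequency (`vcf_min` only).
#' @param population Population tag stored on every record (default `"ALL"`,
#'   the averaged world population).
#' @return A tibble with columns `rsid`, `chrom`, `pos` (1-based), `major`,
#'   `minor`, `maf`, `common`, `population`.
#' @examples
#' read_snp_table(c("chr1\t150\trs1\tG\tA\t.\t.\tAF=0.12"), dialect = "vcf_min")
#' @export
read_snp_table <- function(file, dialect = c("vcf_min", "tsv"),
                           af_key = "AF", population = "ALL") {
  dialect <- match.arg(dialect)
  lines <- if (is.character(file) && (length(file) > 1L ||
                                      (!file.exists(file[1]) && grepl("[\n\t]", file[1])))) {
    unlist(strsplit(file, "\n"))
  } else readr::read_lines(file)
  if (dialect == "tsv") {
    return(parse_snp_tsv(lines, population))
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_snp_tbl())
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 5L) {
      abort(paste0("VCF line ", i, " has fewer than 5 fields"),
            class = "rsnpscan_format_error")
    }
    chrom <- f[1]; pos <- suppressWarnings(as.integer(f[2]))
    rsid <- f[3]; ref <- toupper(f[4])
    alts <- toupper(strsplit(f[5], ",", fixed = TRUE)[[1]])
    info <- if (length(f) >= 8L) f[8] else if (length(f) == 6L) f[6] else f[length(f)]
    if (is.na(pos)) {
      abort(paste0("VCF line ", i, ": unparsable POS '", f[2], "'"),
            class = "rsnpscan_format_error")
    }
    afs <- parse_info_af(info, af_key, n_alt = length(alts), line = i)
    # multi-allelic: keep the most frequent ALT
    if (length(alts) > 1L) {
      k <- which.max(afs)
      inform(paste0("Multi-allelic record ", rsid, " reduced to ALT '",
                    alts[k], "' (AF = ", afs[k], ")"))
      alts <- alts[k]; afs <- afs[k]
    }
    alt <- alts[1]; af <- afs[1]
    if (!ref %in% DNA_BASES || !alt %in% DNA_BASES) {
      warn(paste0("Skipping ", rsid, ": REF/ALT not single bases (",
                  ref, "/", alt, ")"))
      return(NULL)
    }
    if (ref == alt) {
      warn(paste0("Skipping ", rsid, ": REF equals ALT"))
      return(NULL)
    }
    major <- ref; minor <- alt; maf <- af
    if (af > 0.5) {
      major <- alt; minor <- ref; maf <- 1 - af
      inform(paste0("Record ", rsid, ": ALT frequency ", af,
                    " > 0.5; ALT taken as major allele"))
    }
    tibble(rsid = rsid, chrom = chrom, pos = pos,
           major = major, minor = minor, maf = maf)
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) return(empty_snp_tbl())
  out$common <- out$maf > 0.01
  out$population <- population
  out
}

parse_info_af <- function(info, af_key, n_alt, line) {
  keyvals <- strsplit(info, ";", fixed = TRUE)[[1]]
  hit <- grep(paste0("^", af_key, "="), keyvals, value = TRUE)
  if (length(hit) == 0L) {
    abort(paste0("VCF line ", line, ": INFO key '", af_key, "' not found"),
          class = "rsnpscan_format_error")
  }
  vals <- suppressWarnings(
    as.numeric(strsplit(sub("^[^=]+=", "", hit[1]), ",", fixed = TRUE)[[1]]))
  if (anyNA(vals) || length(vals) != n_alt) {
    abort(paste0("VCF line ", line, ": unparsable allele frequency in '",
                 hit[1], "'"),
          class = "rsnpscan_format_error")
  }
  vals
}

parse_snp_tsv <- function(lines, population) {
  if (length(lines) == 0L || all(!nzchar(lines))) return(empty_snp_tbl())
  # read everything as character: allele columns holding only "T" or "F"
  # must not be guessed as logicals
  tbl <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                         col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE, progress = FALSE)
  names(tbl) <- tolower(names(tbl))
  aliases <- c(rsid = "id", chrom = "chr", major = "major_allele",
               minor = "minor_allele", maf = "freq")
  for (want in names(aliases)) {
    if (!want %in% names(tbl) && aliases[[want]] %in% names(tbl)) {
      names(tbl)[names(tbl) == aliases[[want]]] <- want
    }
  }
  need <- c("rsid", "chrom", "pos", "major", "minor", "maf")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(paste0("SNP TSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "rsnpscan_format_error")
  }
  tbl <- dplyr::mutate(tbl,
    rsid = as.character(.data$rsid),
    chrom = as.character(.data$chrom),
    pos = as.integer(.data$pos),
    major = toupper(.data$major),
    minor = toupper(.data$minor),
    maf = as.numeric(.data$maf))
  if (anyNA(tbl$maf)) {
    abort("SNP TSV contains unparsable maf values",
          class = "rsnpscan_format_error")
  }
  bad <- !(tbl$major %in% DNA_BASES) | !(tbl$minor %in% DNA_BASES) |
    tbl$major == tbl$minor
  if (any(bad)) {
    warn(paste0("Skipping ", sum(bad), " record(s) with invalid alleles: ",
                paste(tbl$rsid[bad], collapse = ", ")))
    tbl <- tbl[!bad, , drop = FALSE]
  }
  tbl$common <- tbl$maf > 0.01
  tbl$population <- if ("population" %in% names(tbl)) {
    as.character(tbl$population)
  } else population
  dplyr::select(tbl, "rsid", "chrom", "pos", "major", "minor", "maf",
                "common", "population")
}

empty_snp_tbl <- function() {
  tibble(rsid = character(), chrom = character(), pos = integer(),
         major = character(), minor = character(), maf = numeric(),
         common = logical(), population = character())
}

#' Write a SNP table as TSV
#'
#' Companion writer for [read_snp_table()]'s `tsv` dialect.
#'
#' @param snps Tibble as returned by [read_snp_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  readr::write_tsv(snps[, c("rsid", "chrom", "pos", "major", "minor", "maf")],
                   path, progress = FALSE)
  invisible(path)
}
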