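#' Write and read rSNP call tables
#'
#' `write_calls_tsv()` renders calls in the study's report layout — columns
#' `Gene`, `rSNP`, `CellLine`, `TF`, `RBS_M`, `RBSm`, `AffinityImpactPct`,
#' `HR`, `HWF`, `FIF`, `Category` — with numeric fields rounded to 2 decimals
#' (internal values keep full precision; rounding happens only here).
#' `read_calls_tsv()` parses that layout back into an `rsnp_calls` tibble, so
#' write–read round-trips on 2-decimal data.
#'
#' @param calls An `rsnp_calls` tibble (or any tibble with the same columns).
#' @param path Output/input file path (`write` also accepts a connection).
#' @return `write_calls_tsv()`: `path`, invisibly. `read_calls_tsv()`: an
#'   `rsnp_calls` tibble.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- tibble(
    Gene = as.character(calls$gene),
    rSNP = as.character(calls$rsid),
    CellLine = as.character(calls$cell_line),
    TF = as.character(calls$tf),
    RBS_M = sprintf("%.2f", calls$rbs_major),
    RBSm = sprintf("%.2f", calls$rbs_minor),
    AffinityImpactPct = sprintf("%.2f", calls$affinity_impact_pct),
    HR = as.integer(calls$hr),
    HWF = sprintf("%.2f", calls$hwf),
    FIF = sprintf("%.2f", calls$fif),
    Category = as.character(calls$category))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("Gene", "rSNP", "CellLine", "TF", "RBS_M", "RBSm",
            "AffinityImpactPct", "HR", "HWF", "FIF", "Category")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(paste0("Calls TSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "rsnpscan_format_error")
  }
  out <- tibble(
    gene = tbl$Gene, rsid = tbl$rSNP, cell_line = tbl$CellLine, tf = tbl$TF,
    rbs_major = as.numeric(tbl$RBS_M), rbs_minor = as.numeric(tbl$RBSm),
    affinity_impact_pct = as.numeric(tbl$AffinityImpactPct),
    hr = as.integer(tbl$HR), hwf = as.numeric(tbl$HWF),
    fif = as.numeric(tbl$FIF),
    category = factor(tbl$Category,
                      levels = c("decreased_affinity", "increased_affinity",
                                 "new_tfbs_suggested", "below_threshold")))
  new_rsnp_calls(out)
}
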