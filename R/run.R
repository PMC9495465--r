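#' Pipeline runs: simulate, scan, confirm
#'
#' Three deterministic entry points orchestrating the package's stages on
#' files, mirroring a typical run of the prediction tool. A thin
#' command-line wrapper over these functions ships in
#' `system.file("cli", "rsnpscan.R", package = "rsnpscan")`.
#'
#' `run_simulate()` writes a complete synthetic fixture (genome FASTA, SNP
#' and gene TSVs, per-cell-line DNase BED, JASPAR-text PFMs, planted truth,
#' YAML manifest) into a directory.
#'
#' `run_scan()` reads those standard formats (from a fixture directory or
#' explicit paths), builds the pseudo-promoters, scans and scores, and
#' writes the calls TSV. Malformed inputs raise classed errors naming the
#' offending file.
#'
#' `run_confirm()` joins a calls TSV with an evidence TSV, applies the
#' confirmation rules, and returns the summary; rsids present in only one
#' file are listed as unmatched in the summary.
#'
#' @param out_dir Directory to write the fixture into.
#' @param seed Integer seed.
#' @param ... For `run_simulate()`: passed to [generate_fixture()].
#' @return `run_simulate()`: the `synthetic_fixture`, invisibly.
#' @name pipeline-runs
NULL

#' @rdname pipeline-runs
#' @export
run_simulate <- function(out_dir, seed, ...) {
  fx <- generate_fixture(..., seed = seed, out_dir = out_dir)
  invisible(fx)
}

#' @rdname pipeline-runs
#' @param dir A fixture directory produced by `run_simulate()`; individual
#'   paths can be overridden.
#' @param genome_fasta,snp_tsv,gene_tsv,pfm_file Input paths (defaulted from
#'   `dir`).
#' @param bed_files Named character vector of BED paths, names = cell lines
#'   (defaulted from the `synthetic_dnase_*.bed` files in `dir`).
#' @param out_tsv If non-`NULL`, the calls are written there via
#'   [write_calls_tsv()].
#' @param cell_line Optional cell-line filter (calls restricted to these).
#' @param config Named list of scoring options overriding the defaults:
#'   `rbs_floor`, `fif_threshold`, `pseudocount`, `gc` (scoring background
#'   via [background_from_gc()]), `promoter_length`, `maf_floor` is implicit
#'   in the common-SNP flag.
#' @return `run_scan()`: the `rsnp_calls` tibble.
#' @export
run_scan <- function(dir = NULL, genome_fasta = NULL, snp_tsv = NULL,
                     gene_tsv = NULL, pfm_file = NULL, bed_files = NULL,
                     out_tsv = NULL, cell_line = NULL, config = list()) {
  pick <- function(x, file) {
    if (!is.null(x)) x else {
      if (is.null(dir)) abort(paste0("either `dir` or `", file, "` is needed"))
      file.path(dir, file)
    }
  }
  genome_fasta <- pick(genome_fasta, "synthetic_genome.fa")
  snp_tsv <- pick(snp_tsv, "synthetic_snps.tsv")
  gene_tsv <- pick(gene_tsv, "synthetic_genes.tsv")
  pfm_file <- pick(pfm_file, "synthetic_pfms.jaspar")
  if (is.null(bed_files)) {
    if (is.null(dir)) abort("either `dir` or `bed_files` is needed")
    found <- list.files(dir, pattern = "^synthetic_dnase_.*\\.bed$",
                        full.names = TRUE)
    bed_files <- setNames(found, sub("^synthetic_dnase_(.*)\\.bed$", "\\1",
                                     basename(found)))
  }
  for (f in c(genome_fasta, snp_tsv, gene_tsv, pfm_file, bed_files)) {
    if (!file.exists(f)) {
      abort(paste0("Input file not found: ", f),
            class = "rsnpscan_missing_input")
    }
  }
  cfg <- utils::modifyList(
    list(rbs_floor = 0.80, fif_threshold = 10, pseudocount = 0.8,
         gc = 0.41, promoter_length = 2000), config)

  genome <- as_genome(genome_fasta)
  snps <- read_snp_table(snp_tsv, dialect = "tsv")
  genes <- readr::read_tsv(gene_tsv, show_col_types = FALSE, progress = FALSE)
  pfms <- read_jaspar_pfm(pfm_file)
  tracks <- dplyr::bind_rows(imap(as.list(bed_files), function(f, cl) {
    read_bed(f, cell_line = cl)
  }))
  if (!is.null(cell_line)) {
    tracks <- tracks[tracks$cell_line %in% cell_line, , drop = FALSE]
  }
  promoters <- lapply(seq_len(nrow(genes)), function(i) {
    spec <- as.list(genes[i, ])
    spec$length <- spec$length %||% cfg$promoter_length
    build_pseudopromoter(spec, genome, snps)
  })
  calls <- call_rsnps(promoters, pfms, tracks,
                      rbs_floor = cfg$rbs_floor,
                      fif_threshold = cfg$fif_threshold,
                      pseudocount = cfg$pseudocount,
                      background = background_from_gc(cfg$gc))
  if (!is.null(out_tsv)) write_calls_tsv(calls, out_tsv)
  calls
}

#' @rdname pipeline-runs
#' @param calls_tsv Path to a calls TSV (layout of [write_calls_tsv()]).
#' @param evidence_tsv Path to an evidence TSV with the columns of
#'   [fd_evidence()] (missing values as `NA` or `ND`).
#' @param rules Confirmation rules ([default_confirm_rules()]).
#' @return `run_confirm()`: a list with `summary` (an `rsnp_summary`),
#'   `confirmed` (per-rsid confirmation tibble) and `calls`.
#' @export
run_confirm <- function(calls_tsv, evidence_tsv = NULL,
                        rules = default_confirm_rules()) {
  calls <- read_calls_tsv(calls_tsv)
  evidence <- if (!is.null(evidence_tsv)) read_evidence_tsv(evidence_tsv)
  summary <- summarize_predictions(calls, evidence)
  confirmed <- if (!is.null(evidence) && nrow(evidence)) {
    confirm_rsnps(evidence, rules)
  } else {
    tibble(rsid = unique(calls$rsid),
           confirmed = FALSE, n_tags = 0L, supporting = "")
  }
  if (length(summary$unmatched_rsids)) {
    warn(paste0("rsid(s) present in only one of calls/evidence: ",
                paste(summary$unmatched_rsids, collapse = ", ")))
  }
  list(summary = summary, confirmed = confirmed, calls = calls)
}

#' Read and write external-evidence tables
#'
#' TSV with the column set of [fd_evidence()]; `ND` and empty cells become
#' `NA`.
#'
#' @param path File path.
#' @return A tibble with the [fd_evidence()] columns.
#' @export
read_evidence_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA", "ND"))
  num_cols <- c("gwava_score", "funseq2_score", "deepsea_eqtl_prob",
                "ensembl_effect_size", "gtex_m_value", "expression_tpm",
                "encode_log2_tpm")
  for (cn in intersect(num_cols, names(tbl))) {
    tbl[[cn]] <- as.numeric(tbl[[cn]])
  }
  if (!"rsid" %in% names(tbl)) {
    abort("Evidence TSV must have an 'rsid' column",
          class = "rsnpscan_format_error")
  }
  tbl
}

#' @rdname read_evidence_tsv
#' @param evidence Evidence tibble.
#' @export
write_evidence_tsv <- function(evidence, path) {
  readr::write_tsv(evidence, path, progress = FALSE)
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' YAML with flat keys (`rbs_floor`, `fif_threshold`, `pseudocount`, `gc`,
#' `promoter_length`, `seed`, `cell_lines`, input paths). Unknown keys are
#' kept and passed through; command-line flags override file values in the
#' CLI wrapper.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path),
          class = "rsnpscan_missing_input")
  }
  yaml::read_yaml(path)
}
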