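#' Packaged study tables: Fabry-disease modifier-gene panel
#'
#' The three tables of the Fabry-disease (FD) modifier-gene promoter study,
#' packaged verbatim as typed tibbles so the downstream arithmetic and
#' aggregation rules can be exercised without any external download.
#'
#' * `fd_gene_panel()` — the 14-gene panel with each gene's selection
#'   category and its number of common promoter SNPs (110 in total).
#' * `fd_rsnp_calls()` — the 27 published (gene, rSNP, cell line, TF) calls
#'   with RBS_M, RBSm, affinity impact %, HR, HWF and FIF exactly as printed.
#'   Two cells of the rs4987025 rows are sign-inconsistent as printed (the
#'   FIF does not equal impact × HWF in sign, only in magnitude); they are
#'   flagged `sign_inconsistent = TRUE` and preserved verbatim. The
#'   `category` column is derived by applying [categorize()] to the printed
#'   FIF (the published table prints no category column).
#' * `fd_evidence()` — the external-evidence table: GWAVA and FunSeq2 scores
#'   and labels, DeepSEA eQTL probabilities, Ensembl eQTL effect sizes, GTEx
#'   m-values and expression levels (TPM/FPKM, plus the log2(TPM/FPKM+0.01)
#'   RNA-seq profile) per SNP and cell line. "No data" cells are `NA`.
#'
#' @return Tibbles; see Details. `fd_rsnp_calls()` carries class
#'   `rsnp_calls`.
#' @examples
#' sum(fd_gene_panel()$n_common_snps)  # 110
#' @name fd_tables
NULL

#' @rdname fd_tables
#' @export
fd_gene_panel <- function() {
  tribble(
    ~category,               ~gene_symbol, ~n_common_snps,
    "interleukins",          "TNF",        3L,
    "interleukins",          "IL10",       8L,
    "interleukins",          "IL1A",       6L,
    "interleukins",          "IL1B",       5L,
    "interleukins",          "IL6",        7L,
    "fibrosis_sclerosis",    "TGFB1",      9L,
    "fibrosis_sclerosis",    "FGF2",       11L,
    "fibrosis_sclerosis",    "MMP1",       9L,
    "renal",                 "REN",        14L,
    "renal",                 "AGTR1",      8L,
    "renal",                 "AGT",        3L,
    "endothelial_vascular",  "EDN1",       8L,
    "endothelial_vascular",  "NOS3",       10L,
    "endothelial_vascular",  "MTHFR",      9L)
}

#' @rdname fd_tables
#' @export
fd_rsnp_calls <- function() {
  tbl <- tribble(
    ~gene,   ~rsid,          ~cell_line, ~tf,         ~rbs_major, ~rbs_minor, ~affinity_impact_pct, ~hr, ~hwf, ~fif,
    "IL10",  "rs76176414",   "Hcm",      "SPIB",      0.87, 0.70, -19.57, 1L, 1,   -19.57,
    "IL10",  "rs76176414",   "Hac",      "BATF::JUN", 0.82, 0.72, -11.54, 1L, 1,   -11.54,
    "IL10",  "rs1800895",    "TH1",      "USF2",      0.94, 0.81, -13.27, 1L, 1,   -13.27,
    "IL10",  "rs1800895",    "TH1",      "MLX",       0.80, 0.68, -15.10, 1L, 1,   -15.10,
    "IL10",  "rs1800895",    "TH1",      "BHLHE41",   0.81, 0.70, -13.42, 1L, 1,   -13.42,
    "IL10",  "rs1800895",    "TH1",      "BHLHE23",   0.87, 0.96,  10.40, 1L, 1,    10.40,
    "IL10",  "rs1800895",    "TH1",      "BHLHE22",   0.86, 0.96,  11.51, 1L, 1,    11.51,
    "TGFB1", "rs1800468",    "Hcm",      "ESRRB",     0.84, 0.73, -12.77, 1L, 1,   -12.77,
    "TGFB1", "rs1800468",    "Hcm",      "GMEB2",     0.83, 0.66, -20.76, 1L, 1,   -20.76,
    "TGFB1", "rs1800468",    "Hcm",      "CREB1",     0.86, 0.73, -15.32, 1L, 1,   -15.32,
    "TGFB1", "rs538246709",  "Huvec",    "LBX1",      0.80, 0.67, -16.15, 1L, 1,   -16.15,
    "TGFB1", "rs538246709",  "Huvec",    "GATA3",     0.86, 0.73, -14.65, 1L, 1,   -14.65,
    "TGFB1", "rs538246709",  "Huvec",    "ZEB1",      0.83, 0.69, -16.54, 1L, 1,   -16.54,
    "TGFB1", "rs4987025",    "Huvec",    "BATF::JUN", 0.80, 0.68, -14.20, 1L, 1,    14.20,
    "TGFB1", "rs4987025",    "Huvec",    "SMAD3",     0.80, 0.70,  12.52, 1L, 1,   -12.52,
    "TGFB1", "rs538246709",  "TH1",      "LBX1",      0.80, 0.67, -16.15, 1L, 1,   -16.15,
    "TGFB1", "rs538246709",  "TH1",      "GATA3",     0.86, 0.73, -14.65, 1L, 1,   -14.65,
    "TGFB1", "rs538246709",  "TH1",      "ZEB1",      0.83, 0.69, -16.54, 1L, 1,   -16.54,
    "EDN1",  "rs879287158",  "TH1",      "CREB1",     0.80, 0.93,  16.53, 1L, 1,    16.53,
    "EDN1",  "rs879287158",  "TH1",      "NOTO",      0.80, 0.61, -23.68, 2L, 0.5, -11.84,
    "EDN1",  "rs572006226",  "Hac",      "HOXD12",    0.81, 0.69, -14.93, 1L, 1,   -14.93,
    "EDN1",  "rs879287158",  "Hcf",      "CREB1",     0.80, 0.93,  16.53, 1L, 1,    16.53,
    "EDN1",  "rs879287158",  "Hcf",      "TCF3",      0.82, 0.65, -20.09, 2L, 0.5, -10.04,
    "EDN1",  "rs879287158",  "Hcm",      "CREB1",     0.80, 0.93,  16.53, 1L, 1,    16.53,
    "EDN1",  "rs879287158",  "Huvec",    "USF1",      0.81, 0.69, -15.61, 1L, 1,   -15.61,
    "EDN1",  "rs879287158",  "Huvec",    "CREB1",     0.80, 0.93,  16.53, 1L, 1,    16.53,
    "EDN1",  "rs879287158",  "Huvec",    "TCF3",      0.82, 0.65, -20.09, 2L, 0.5, -10.04)
  tbl$sign_inconsistent <- sign(tbl$fif) != sign(tbl$affinity_impact_pct)
  tbl$category <- categorize(tbl$fif, tbl$rbs_major, tbl$rbs_minor)
  new_rsnp_calls(tbl)
}

#' @rdname fd_tables
#' @export
fd_evidence <- function() {
  tribble(
    ~gene,   ~rsid,          ~gwava_score, ~gwava_label,  ~funseq2_score, ~funseq2_label, ~deepsea_eqtl_prob, ~cell_line, ~ensembl_effect_size, ~gtex_m_value, ~expression_tpm, ~encode_log2_tpm,
    "IL10",  "rs76176414",   0.32, "neutral",     NA,   NA,            0.68, "Hcm",   NA,   NA, 0.7, 0.01,
    "IL10",  "rs76176414",   0.32, "neutral",     NA,   NA,            0.68, "Hac",   NA,   NA, 0.4, 0.01,
    "IL10",  "rs1800895",    0.33, "neutral",     0,    "neutral",     0.70, "TH1",   0.22, NA, 0.9, 0.37,
    "TGFB1", "rs1800468",    0.78, "deleterious", 0.49, "neutral",     0.64, "Hcm",   0.24, NA, 27,  8.05,
    "TGFB1", "rs538246709",  0.58, "deleterious", 0.49, "neutral",     0.55, "Huvec", NA,   NA, 145, 7.25,
    "TGFB1", "rs4987025",    0.55, "deleterious", 0.49, "neutral",     0.57, "Huvec", NA,   NA, 145, 7.25,
    "TGFB1", "rs538246709",  0.58, "deleterious", 0.49, "neutral",     0.55, "TH1",   NA,   NA, 38,  4.93,
    "EDN1",  "rs879287158",  0.71, "deleterious", 3.22, "deleterious", 0.95, "TH1",   NA,   NA, 2,   1.04,
    "EDN1",  "rs572006226",  0.47, "deleterious", 3.59, "deleterious", NA,   "Hac",   NA,   NA, 6,   5.85,
    "EDN1",  "rs879287158",  0.71, "deleterious", 3.22, "deleterious", 0.95, "Hcf",   NA,   NA, 8,   2.05,
    "EDN1",  "rs879287158",  0.71, "deleterious", 3.22, "deleterious", 0.95, "Hcm",   NA,   NA, 8,   1.18,
    "EDN1",  "rs879287158",  0.71, "deleterious", 3.22, "deleterious", 0.95, "Huvec", NA,   NA, 557, 5.69)
}

#' @rdname fd_tables
#' @return `table_fixtures()`: a list with elements `gene_panel`, `calls`,
#'   `evidence` (the three tables above).
#' @export
table_fixtures <- function() {
  list(gene_panel = fd_gene_panel(),
       calls = fd_rsnp_calls(),
       evidence = fd_evidence())
}
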