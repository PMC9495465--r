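#' eQTL m-value and expression-level categories
#'
#' `mvalue_category()` applies the per-tissue eQTL posterior rule: below 0.1
#' the tissue is predicted to have no eQTL effect, above 0.9 to have one,
#' anything between is indeterminate.
#'
#' `expression_category()` bins TPM/FPKM expression values: below 0.5 is
#' below cutoff, 0.5–10 low, above 10 up to 1000 medium, above 1000 high
#' (the published 10/11 gap between "low" and "medium" is closed at 10).
#'
#' Both are vectorised; each input maps to exactly one category and `NA`
#' propagates.
#'
#' @param m eQTL m-value(s), `>= 0`.
#' @param v Expression value(s) in TPM or FPKM, `>= 0`.
#' @return A factor (`no_eqtl_effect` / `indeterminate` / `eqtl_effect`, or
#'   `below_cutoff` / `low` / `medium` / `high`; the expression factor is
#'   ordered).
#' @examples
#' mvalue_category(c(0.05, 0.5, 0.95))
#' expression_category(c(0.2, 0.7, 145, 1500))
#' @export
mvalue_category <- function(m) {
  stopifnot(all(m >= 0, na.rm = TRUE))
  out <- rep(NA_character_, length(m))
  out[m < 0.1] <- "no_eqtl_effect"
  out[m >= 0.1 & m <= 0.9] <- "indeterminate"
  out[m > 0.9] <- "eqtl_effect"
  factor(out, levels = c("no_eqtl_effect", "indeterminate", "eqtl_effect"))
}

#' @rdname mvalue_category
#' @export
expression_category <- function(v) {
  stopifnot(all(v >= 0, na.rm = TRUE))
  out <- rep(NA_character_, length(v))
  out[v < 0.5] <- "below_cutoff"
  out[v >= 0.5 & v <= 10] <- "low"
  out[v > 10 & v <= 1000] <- "medium"
  out[v > 1000] <- "high"
  factor(out, levels = c("below_cutoff", "low", "medium", "high"),
         ordered = TRUE)
}

#' Default rSNP confirmation rules
#'
#' The any-evidence rule set used by [confirm_rsnp()]: a predicted rSNP is
#' confirmed when at least one clause holds. Each clause has a tag.
#'
#' @param deepsea_cutoff Minimum DeepSEA eQTL probability (default 0.5).
#' @param min_expression Minimum expression category (default `"low"`).
#' @return A named list of rule parameters.
#' @export
default_confirm_rules <- function(deepsea_cutoff = 0.5,
                                  min_expression = "low") {
  list(deepsea_cutoff = deepsea_cutoff, min_expression = min_expression)
}

#' Confirm a predicted rSNP against external evidence
#'
#' Applies the evidence-aggregation rule to all records of one SNP (typically
#' one row per cell line). With the default rules the SNP is confirmed iff ANY
#' of: GWAVA label deleterious; FunSeq2 label deleterious; DeepSEA eQTL
#' probability at or above the cutoff; a GTEx m-value in the `eqtl_effect`
#' band; an Ensembl eQTL effect size present; or an expression value at or
#' above the minimum category in some assayed cell line. The rule is
#' monotone: adding evidence can only add supporting tags, never withdraw
#' confirmation.
#'
#' @param ev Evidence tibble for a single rsid (columns as in
#'   [fd_evidence()]: `rsid`, `gwava_label`, `funseq2_label`,
#'   `deepsea_eqtl_prob`, `ensembl_effect_size`, `gtex_m_value`,
#'   `expression_tpm`, ...; absent evidence is `NA`). Every record must carry
#'   at least one non-missing evidence field.
#' @param rules Rule parameters from [default_confirm_rules()].
#' @return A list with `confirmed` (logical scalar) and `supporting`
#'   (character vector of satisfied-clause tags, possibly empty).
#' @export
confirm_rsnp <- function(ev, rules = default_confirm_rules()) {
  if (nrow(ev) == 0L) abort("evidence for a SNP must be non-empty")
  if (length(unique(ev$rsid)) != 1L) {
    abort("confirm_rsnp() takes the records of a single rsid")
  }
  fields <- setdiff(names(ev), c("rsid", "gene", "cell_line"))
  has_any <- apply(!is.na(ev[, fields, drop = FALSE]), 1, any)
  if (!all(has_any)) {
    abort(paste0("Evidence record(s) for ", ev$rsid[1],
                 " carry no evidence fields"))
  }
  tags <- character(0)
  lbl <- function(col) !is.na(ev[[col]]) & ev[[col]] == "deleterious"
  if ("gwava_label" %in% names(ev) && any(lbl("gwava_label"))) {
    tags <- c(tags, "gwava_deleterious")
  }
  if ("funseq2_label" %in% names(ev) && any(lbl("funseq2_label"))) {
    tags <- c(tags, "funseq2_deleterious")
  }
  if ("deepsea_eqtl_prob" %in% names(ev) &&
      any(ev$deepsea_eqtl_prob >= rules$deepsea_cutoff, na.rm = TRUE)) {
    tags <- c(tags, "deepsea_eqtl")
  }
  if ("gtex_m_value" %in% names(ev) &&
      any(mvalue_category(ev$gtex_m_value[!is.na(ev$gtex_m_value)]) ==
            "eqtl_effect")) {
    tags <- c(tags, "gtex_eqtl")
  }
  if ("ensembl_effect_size" %in% names(ev) &&
      any(!is.na(ev$ensembl_effect_size))) {
    tags <- c(tags, "ensembl_effect")
  }
  if ("expression_tpm" %in% names(ev)) {
    cat_ok <- expression_category(ev$expression_tpm[!is.na(ev$expression_tpm)])
    if (any(cat_ok >= rules$min_expression)) {
      tags <- c(tags, "expression")
    }
  }
  list(confirmed = length(tags) > 0L, supporting = tags)
}

#' @rdname confirm_rsnp
#' @param evidence Evidence tibble covering any number of rsids.
#' @return `confirm_rsnps()`: a tibble with one row per rsid — `rsid`,
#'   `confirmed`, `n_tags`, `supporting` (comma-separated tags).
#' @export
confirm_rsnps <- function(evidence, rules = default_confirm_rules()) {
  rsids <- unique(evidence$rsid)
  purrr::map(rsids, function(r) {
    res <- confirm_rsnp(evidence[evidence$rsid == r, , drop = FALSE], rules)
    tibble(rsid = r, confirmed = res$confirmed,
           n_tags = length(res$supporting),
           supporting = paste(res$supporting, collapse = ","))
  }) |> purrr::list_rbind()
}

#' Summarise rSNP predictions and their external support
#'
#' Aggregates a call table and an evidence table into the study's headline
#' numbers: distinct predicted rSNPs, genes and cell lines, the fraction of
#' distinct rSNPs labelled deleterious by GWAVA, and per-gene rSNP lists.
#'
#' @param calls An `rsnp_calls` tibble (possibly empty).
#' @param evidence Evidence tibble (possibly empty); rsids present in only
#'   one of the two tables are listed as unmatched.
#' @return An object of class `rsnp_summary`: a list with `n_rsnps`,
#'   `n_genes`, `n_cell_lines`, `gwava_deleterious_frac` (`NA` when no GWAVA
#'   labels), `per_gene` (tibble `gene`, `rsids`, `n`), and
#'   `unmatched_rsids`. [glance()] returns the counts as a one-row tibble;
#'   [tidy()] returns the per-gene table.
#' @export
summarize_predictions <- function(calls, evidence = NULL) {
  calls <- as_tibble(calls)
  n_rsnps <- dplyr::n_distinct(calls$rsid)
  per_gene <- if (nrow(calls)) {
    calls |>
      dplyr::distinct(.data$gene, .data$rsid) |>
      dplyr::arrange(.data$gene, .data$rsid) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(rsids = paste(.data$rsid, collapse = ","),
                       n = dplyr::n(), .groups = "drop")
  } else {
    tibble(gene = character(), rsids = character(), n = integer())
  }
  gw_frac <- NA_real_
  unmatched <- character(0)
  if (!is.null(evidence) && nrow(evidence)) {
    lab <- evidence |>
      dplyr::filter(!is.na(.data$gwava_label)) |>
      dplyr::distinct(.data$rsid, .data$gwava_label)
    if (nrow(lab)) {
      gw_frac <- mean(tapply(lab$gwava_label == "deleterious", lab$rsid, any))
    }
    unmatched <- sort(unique(c(
      setdiff(calls$rsid, evidence$rsid),
      setdiff(evidence$rsid, calls$rsid))))
  } else if (nrow(calls)) {
    unmatched <- sort(unique(calls$rsid))
  }
  structure(
    list(n_rsnps = n_rsnps,
         n_genes = dplyr::n_distinct(calls$gene),
         n_cell_lines = dplyr::n_distinct(calls$cell_line),
         gwava_deleterious_frac = gw_frac,
         per_gene = per_gene,
         unmatched_rsids = unmatched),
    class = "rsnp_summary"
  )
}

#' @export
print.rsnp_summary <- function(x, ...) {
  cat("rSNP prediction summary\n",
      "  distinct rSNPs: ", x$n_rsnps, "\n",
      "  genes:          ", x$n_genes, "\n",
      "  cell lines:     ", x$n_cell_lines, "\n", sep = "")
  if (!is.na(x$gwava_deleterious_frac)) {
    cat("  GWAVA-deleterious fraction: ",
        sprintf("%.1f%%", 100 * x$gwava_deleterious_frac), "\n", sep = "")
  }
  if (nrow(x$per_gene)) {
    cat("  per gene:\n")
    for (i in seq_len(nrow(x$per_gene))) {
      cat("    ", x$per_gene$gene[i], ": ", x$per_gene$rsids[i], "\n", sep = "")
    }
  }
  if (length(x$unmatched_rsids)) {
    cat("  unmatched rsids: ", paste(x$unmatched_rsids, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
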