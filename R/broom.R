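#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for call tables and prediction summaries
#'
#' `glance()` on an `rsnp_calls` table gives its one-row headline: number of
#' rows, distinct rSNPs, genes, cell lines and TFs, and the per-category
#' call counts. `tidy()` on an `rsnp_summary` returns the per-gene rSNP
#' table; `glance()` returns the summary counts as one row.
#'
#' @param x An `rsnp_calls` tibble or an `rsnp_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.rsnp_calls <- function(x, ...) {
  tibble(
    n_calls = nrow(x),
    n_rsnps = dplyr::n_distinct(x$rsid),
    n_genes = dplyr::n_distinct(x$gene),
    n_cell_lines = dplyr::n_distinct(x$cell_line),
    n_tfs = dplyr::n_distinct(x$tf),
    n_decreased = sum(x$category == "decreased_affinity"),
    n_increased = sum(x$category == "increased_affinity"),
    n_new_tfbs = sum(x$category == "new_tfbs_suggested"))
}

#' @rdname glance.rsnp_calls
#' @export
tidy.rsnp_summary <- function(x, ...) x$per_gene

#' @rdname glance.rsnp_calls
#' @export
glance.rsnp_summary <- function(x, ...) {
  tibble(n_rsnps = x$n_rsnps, n_genes = x$n_genes,
         n_cell_lines = x$n_cell_lines,
         gwava_deleterious_frac = x$gwava_deleterious_frac)
}
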