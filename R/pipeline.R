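#' dtcsig: consensus drug-tolerance signatures
#'
#' End-to-end computational pipeline for characterizing drug-tolerant
#' persister cells from bulk and single-cell RNA-seq: per-model
#' negative-binomial differential expression, m-of-n cross-model consensus
#' signatures (DTC_UP/DTC_DOWN), permutation-based gene-set enrichment with
#' cross-model sharing tables, per-cell UMI-fraction scoring and cluster
#' profiling, pseudo-bulk aggregation, and FUCCI cell-cycle fate analytics,
#' plus synthetic-data generators with planted ground truth.
#'
#' @keywords internal
"_PACKAGE"

#' Per-model differential expression and consensus in one call
#'
#' Runs [nb_wald_test()] on every model of a multi-model experiment and
#' feeds the per-model tables to [build_consensus()].
#'
#' @param models named list of count matrices, one per model.
#' @param sheet combined sample sheet with sample_id, model_id, condition.
#' @param contrast length-2 character vector `c(treated, control)`.
#' @param ... passed to [build_consensus()] (alpha, lfc_threshold,
#'   min_support, universe).
#' @return list with `tables` (per-model `de_table`s) and `signature`
#'   (the `consensus_signature`).
#' @examples
#' \donttest{
#' sim <- simulate_bulk_models(bulk_sim_config(genes_total = 400,
#'                                             n_up_planted = 20,
#'                                             n_down_planted = 20))
#' res <- consensus_from_models(sim$models, sim$sheet, c("DTC", "control"))
#' res$signature
#' }
#' @export
consensus_from_models <- function(models, sheet, contrast, ...) {
  if (is.null(names(models))) names(models) <- sprintf("model%d", seq_along(models))
  tables <- lapply(names(models), function(m) {
    sub <- sheet[sheet$model_id == m, , drop = FALSE]
    nb_wald_test(models[[m]], sub, contrast, model_id = m)
  })
  list(tables = tables, signature = build_consensus(tables, ...))
}
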