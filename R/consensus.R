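#' Build an m-of-n consensus differential-expression signature
#'
#' A gene enters the up signature when it passes `p_value < alpha` and
#' `log2fc > lfc_threshold` in at least `min_support` of the supplied
#' per-model DE tables (down symmetric, `log2fc < -lfc_threshold`). Genes
#' absent from a model's table (or untested, p = NA) count as non-supporting
#' in that model. The per-gene `mean_log2fc` averages over all models in
#' which the gene was tested, supporting or not.
#'
#' @param tables list of `de_table`s (one per model).
#' @param alpha per-model p-value threshold (default 0.01).
#' @param lfc_threshold per-model |log2FC| threshold (default 0.5).
#' @param min_support minimum number of supporting models (default 6).
#' @param universe `"intersection"` (default) restricts candidate genes to
#'   those tested in every model; `"union"` considers any gene tested
#'   anywhere, absent models counting as non-supporting.
#' @return a `consensus_signature`: list with data.frames `up` and `down`
#'   (columns gene, support, mean_log2fc), per-model `lfc` and `p` matrices,
#'   and the parameters used.
#' @export
build_consensus <- function(tables, alpha = 0.01, lfc_threshold = 0.5,
                            min_support = 6, universe = c("intersection", "union")) {
  universe <- match.arg(universe)
  if (length(tables) < 2L) stop("need at least 2 DE tables")
  if (min_support > length(tables)) {
    stop(sprintf("min_support (%d) exceeds number of models (%d)",
                 min_support, length(tables)))
  }
  model_ids <- vapply(tables, function(t) t$model_id[1L], character(1))
  if (anyDuplicated(model_ids)) model_ids <- make.unique(model_ids)

  gene_lists <- lapply(tables, `[[`, "gene")
  genes <- if (universe == "intersection") {
    Reduce(intersect, gene_lists)
  } else {
    Reduce(union, gene_lists)
  }
  genes <- sort(genes)
  if (length(genes) == 0L) stop("empty gene universe across models")

  nm <- length(tables)
  lfc <- matrix(NA_real_, length(genes), nm, dimnames = list(genes, model_ids))
  pmat <- lfc
  for (k in seq_len(nm)) {
    t <- tables[[k]]
    idx <- match(genes, t$gene)
    lfc[, k] <- t$log2fc[idx]
    pmat[, k] <- t$p_value[idx]
  }
  sup_mat <- !is.na(pmat) & !is.na(lfc) & pmat < alpha
  up_support <- rowSums(sup_mat & lfc > lfc_threshold)
  down_support <- rowSums(sup_mat & lfc < -lfc_threshold)
  mean_lfc <- rowMeans(lfc, na.rm = TRUE)

  mk <- function(sel, support) {
    df <- data.frame(gene = genes[sel], support = support[sel],
                     mean_log2fc = mean_lfc[sel], stringsAsFactors = FALSE)
    df[order(df$gene), , drop = FALSE]
  }
  up_sel <- up_support >= min_support
  down_sel <- down_support >= min_support & !up_sel  # disjoint by construction anyway
  out <- list(
    up = mk(up_sel, up_support),
    down = mk(down_sel, down_support),
    lfc = lfc, p = pmat,
    params = list(alpha = alpha, lfc_threshold = lfc_threshold,
                  min_support = min_support, n_models = nm, universe = universe)
  )
  class(out) <- "consensus_signature"
  out
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat(sprintf(
    "consensus_signature: %d up / %d down genes (p < %g, |log2FC| > %g in >= %d of %d models)\n",
    nrow(x$up), nrow(x$down), x$params$alpha, x$params$lfc_threshold,
    x$params$min_support, x$params$n_models
  ))
  invisible(x)
}

#' Rank signature genes by mean log2 fold change
#'
#' Orders the combined up+down signature by `mean_log2fc`, descending, ties
#' broken lexicographically by gene symbol.
#'
#' @param sig a `consensus_signature`.
#' @return data.frame gene, direction, support, mean_log2fc in rank order.
#' @export
rank_by_mean_lfc <- function(sig) {
  stopifnot(inherits(sig, "consensus_signature"))
  if (nrow(sig$up) + nrow(sig$down) == 0L) stop("empty signature")
  df <- rbind(
    if (nrow(sig$up)) cbind(sig$up, direction = "up"),
    if (nrow(sig$down)) cbind(sig$down, direction = "down")
  )
  df <- df[order(-df$mean_log2fc, df$gene), c("gene", "direction", "support", "mean_log2fc")]
  rownames(df) <- NULL
  df
}

#' Overlap of a consensus signature with an external cohort comparison
#'
#' Counts how many signature genes meet the same (alpha, lfc_threshold)
#' criterion, in the given direction, in an independent cohort's DE table
#' (e.g. normal lung vs tumor). Signature genes missing from the cohort table
#' count as non-overlapping but are reported.
#'
#' @param sig a `consensus_signature`.
#' @param cohort_de a `de_table` for the comparison cohort.
#' @param direction `"up"` or `"down"` (which side of the signature to test).
#' @param alpha,lfc_threshold cohort significance criterion (defaults reuse
#'   the signature's 0.01 / 0.5 rule).
#' @return an `overlap_report`: list with `n_signature`, `n_overlap`,
#'   `percent_overlap`, `overlapping_genes`, `missing_genes`, `criterion`.
#' @export
overlap_with_cohort <- function(sig, cohort_de, direction = c("up", "down"),
                                alpha = 0.01, lfc_threshold = 0.5) {
  stopifnot(inherits(sig, "consensus_signature"))
  direction <- match.arg(direction)
  sig_genes <- if (direction == "up") sig$up$gene else sig$down$gene
  if (length(sig_genes) == 0L) stop("empty signature side: ", direction)
  idx <- match(sig_genes, cohort_de$gene)
  missing <- sig_genes[is.na(idx)]
  present <- !is.na(idx)
  lfc <- cohort_de$log2fc[idx[present]]
  p <- cohort_de$p_value[idx[present]]
  hit <- !is.na(p) & !is.na(lfc) & p < alpha &
    (if (direction == "up") lfc > lfc_threshold else lfc < -lfc_threshold)
  n_overlap <- sum(hit)
  out <- list(
    n_signature = length(sig_genes),
    n_overlap = n_overlap,
    percent_overlap = 100 * n_overlap / length(sig_genes),
    overlapping_genes = sig_genes[present][hit],
    missing_genes = missing,
    criterion = list(alpha = alpha, lfc_threshold = lfc_threshold,
                     direction = direction)
  )
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("%d/%d (%.1f%%) signature genes meet the cohort criterion (%s, p < %g, |log2FC| > %g)\n",
              x$n_overlap, x$n_signature, x$percent_overlap,
              x$criterion$direction, x$criterion$alpha, x$criterion$lfc_threshold))
  invisible(x)
}

#' Export a consensus signature as GMT sets
#'
#' Writes the up and down gene lists as two sets (default names `DTC_UP`,
#' `DTC_DOWN`) plus a companion TSV with per-gene support and mean log2FC.
#'
#' @param sig a `consensus_signature`.
#' @param path GMT output path; the companion TSV replaces the extension.
#' @param set_names length-2 names for the up and down sets.
#' @export
write_signature <- function(sig, path, set_names = c("DTC_UP", "DTC_DOWN")) {
  stopifnot(inherits(sig, "consensus_signature"))
  sets <- list()
  if (nrow(sig$up)) sets[[set_names[1L]]] <- sig$up$gene
  if (nrow(sig$down)) sets[[set_names[2L]]] <- sig$down$gene
  if (length(sets)) write_gmt(sets, path)
  tsv <- sub("\\.gmt$", ".tsv", path)
  if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
  df <- rank_by_mean_lfc(sig)
  con <- file(tsv, "w")
  writeLines("# dtcsig consensus signature", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
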