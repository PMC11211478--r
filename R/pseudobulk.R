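#' Random-partition pseudo-bulk aggregation
#'
#' Within each condition, cells are shuffled and dealt round-robin into `k`
#' groups (sizes differing by at most one), and each group's counts are
#' summed into one pseudo-replicate. The resulting pseudo-samples can be fed
#' straight to [nb_wald_test()], turning single-cell data into a
#' replicate-level bulk comparison. Gene-wise totals are conserved exactly.
#'
#' @param umi genes x cells count matrix.
#' @param conditions per-cell condition labels, named by cell id or aligned
#'   with the matrix columns.
#' @param k number of pseudo-replicates per condition (default 3).
#' @param seed integer seed for the shuffles.
#' @return list with `counts` (genes x pseudo-samples `count_matrix`),
#'   `sheet` (sample sheet), and `design` (data.frame cell_id, condition,
#'   group).
#' @export
partition_and_sum <- function(umi, conditions, k = 3, seed = 1) {
  umi <- ensure_counts(umi)
  if (!is.null(names(conditions))) {
    if (!all(colnames(umi) %in% names(conditions))) {
      stop("every cell must have a condition label")
    }
    conditions <- conditions[colnames(umi)]
  } else if (length(conditions) != ncol(umi)) {
    stop("condition labels must cover every cell")
  }
  conditions <- as.character(conditions)
  if (k < 1) stop("k must be >= 1")
  tab <- table(conditions)
  if (any(tab < k)) {
    stop(sprintf("condition(s) with fewer than k = %d cells: %s", k,
                 paste(names(tab)[tab < k], collapse = ", ")))
  }
  with_seed(seed, {
    design <- list()
    cols <- list()
    sheet <- list()
    for (cond in sort(unique(conditions))) {
      cells <- colnames(umi)[conditions == cond]
      shuffled <- sample(cells)
      group <- rep_len(seq_len(k), length(shuffled))   # round-robin: sizes differ <= 1
      design[[cond]] <- data.frame(cell_id = shuffled, condition = cond,
                                   group = group, stringsAsFactors = FALSE)
      for (g in seq_len(k)) {
        sid <- sprintf("%s_rep%d", cond, g)
        cols[[sid]] <- rowSums(umi[, shuffled[group == g], drop = FALSE])
        sheet[[sid]] <- data.frame(sample_id = sid, model_id = "pseudobulk",
                                   condition = cond, stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- rownames(umi)
    list(
      counts = as_count_matrix(counts),
      sheet = do.call(rbind, c(unname(sheet), list(make.row.names = FALSE))),
      design = do.call(rbind, c(unname(design), list(make.row.names = FALSE)))
    )
  })
}
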