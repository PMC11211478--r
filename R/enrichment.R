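#' Rank genes for enrichment analysis
#'
#' Produces the descending ranked list fed to the running-sum enrichment
#' statistic. Metrics: `signed_log2fc` (the log2 fold change itself) or
#' `signed_logp` (sign(log2fc) * -log10(p)). Ties are broken
#' lexicographically by gene symbol so rankings are reproducible.
#'
#' @param table a `de_table`.
#' @param metric ranking metric.
#' @return named numeric vector of scores, sorted descending.
#' @export
rank_genes <- function(table, metric = c("signed_log2fc", "signed_logp")) {
  metric <- match.arg(metric)
  score <- switch(metric,
    signed_log2fc = table$log2fc,
    signed_logp = sign(table$log2fc) * -log10(pmax(table$p_value, 1e-300))
  )
  keep <- is.finite(score)
  score <- score[keep]
  genes <- table$gene[keep]
  ord <- order(-score, genes)
  setNames(score[ord], genes[ord])
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running sum on a ranked gene list: walking down the ranking,
#' set members ("hits") increment the sum by |score|^weight_p normalized by
#' the total over hits, non-members decrement by 1/(N - n_set). The
#' enrichment score is the signed extremum of the running sum.
#'
#' @param ranked named numeric vector from [rank_genes()] (descending).
#' @param set character vector of member gene symbols.
#' @param weight_p hit-weight exponent (0 = unweighted KS, 1 = classic
#'   weighted, the default).
#' @return list with `es` (scalar in \[-1, 1\]) and `running` (the full
#'   running-sum profile, one value per ranked gene).
#' @export
enrichment_score <- function(ranked, set, weight_p = 1) {
  N <- length(ranked)
  hit <- names(ranked) %in% toupper(set)
  n_set <- sum(hit)
  if (n_set == 0L) stop("no gene of the set is present in the ranked universe")
  w <- abs(ranked)^weight_p
  w[!hit] <- 0
  tot <- sum(w)
  if (tot == 0) { w[hit] <- 1; tot <- n_set }  # all-zero scores: fall back to unweighted
  inc <- w / tot
  miss_pen <- if (N > n_set) 1 / (N - n_set) else 0
  running <- cumsum(ifelse(hit, inc, -miss_pen))
  hi <- max(running)
  lo <- min(running)
  es <- if (hi >= -lo) hi else lo   # ties resolve toward the positive extremum
  list(es = es, running = running)
}

# enrichment score from sorted hit positions only, O(n_set); used for
# permutation nulls where the full profile is not needed
es_from_positions <- function(pos, weights_abs, N) {
  k <- length(pos)
  pos <- sort.int(pos)
  w <- weights_abs[pos]
  tot <- sum(w)
  if (tot == 0) w[] <- 1 / k else w <- w / tot
  cw <- cumsum(w)
  miss_pen <- if (N > k) 1 / (N - k) else 0
  after <- cw - (pos - seq_len(k)) * miss_pen        # running sum just after each hit
  before <- c(0, cw[-k]) - (pos - seq_len(k)) * miss_pen  # just before each hit
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Permutation-normalized enrichment score and nominal p-value
#'
#' Gene-label permutations: `n_perm` random sets of the same size are drawn
#' from the ranked universe. NES is the observed score divided by the mean
#' |null score| of matching sign; the nominal p is the +1-corrected fraction
#' of same-sign null scores at least as extreme. Deterministic given `seed`.
#'
#' @param ranked named numeric vector from [rank_genes()].
#' @param set character vector of member gene symbols.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param weight_p hit-weight exponent.
#' @param set_name,model_id labels stamped into the result.
#' @return an `enrichment_result` data.frame row: set_name, es, nes,
#'   nominal_p, direction, model_id, n_genes.
#' @export
nes_and_p <- function(ranked, set, n_perm = 1000, seed = 1, weight_p = 1,
                      set_name = "set", model_id = "model1") {
  if (n_perm < 100) stop("n_perm must be >= 100")
  obs <- enrichment_score(ranked, set, weight_p)$es
  N <- length(ranked)
  k <- sum(names(ranked) %in% toupper(set))
  wabs <- abs(ranked)^weight_p
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      es_from_positions(sample.int(N, k), wabs, N)
    }, numeric(1))
  })
  same <- null_es[sign(null_es) == sign(obs)]
  if (length(same) == 0L) {
    nes <- NA_real_
    p <- 1 / (1 + n_perm)
  } else {
    nes <- obs / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(obs))) / (1 + length(same))
  }
  direction <- if (!is.na(nes) && nes > 1) "up" else if (!is.na(nes) && nes < -1) "down" else "none"
  out <- data.frame(set_name = set_name, es = obs, nes = nes, nominal_p = p,
                    direction = direction, model_id = model_id, n_genes = k,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment of a gene-set collection in one ranked list
#'
#' Convenience wrapper running [nes_and_p()] for every set of a collection.
#'
#' @param ranked named numeric vector from [rank_genes()].
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @inheritParams nes_and_p
#' @return an `enrichment_result` data.frame, one row per set with at least
#'   one member in the universe (sets with none are dropped with a warning).
#' @export
enrich_collection <- function(ranked, collection, n_perm = 1000, seed = 1,
                              weight_p = 1, model_id = "model1") {
  rows <- list()
  for (nm in names(collection)) {
    if (!any(names(ranked) %in% toupper(collection[[nm]]))) {
      warning(sprintf("set '%s' has no member in the ranked universe; skipped", nm))
      next
    }
    rows[[nm]] <- nes_and_p(ranked, collection[[nm]], n_perm = n_perm,
                            seed = seed + length(rows), weight_p = weight_p,
                            set_name = nm, model_id = model_id)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Cross-model sharing of enriched gene sets
#'
#' For each gene set, counts in how many models it is significantly enriched
#' up (nominal p below threshold and NES > 1) and down (NES < -1), the
#' tabulation behind "how many of the n models share this signature".
#'
#' @param results an `enrichment_result` data.frame covering one or more
#'   models (rbind of per-model results).
#' @param p_threshold nominal p-value threshold (default 0.05).
#' @return data.frame set_name, n_models_up, n_models_down, sorted by total
#'   sharing (descending).
#' @export
sharing_count <- function(results, p_threshold = 0.05) {
  if (nrow(results) == 0L) stop("no enrichment results supplied")
  sig_up <- results$nominal_p < p_threshold & !is.na(results$nes) & results$nes > 1
  sig_down <- results$nominal_p < p_threshold & !is.na(results$nes) & results$nes < -1
  up <- tapply(sig_up, results$set_name, sum)
  down <- tapply(sig_down, results$set_name, sum)
  sets <- sort(unique(results$set_name))
  out <- data.frame(
    set_name = sets,
    n_models_up = as.integer(up[sets]),
    n_models_down = as.integer(down[sets]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-(out$n_models_up + out$n_models_down), out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
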