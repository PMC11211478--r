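#' Median-of-ratios size factors
#'
#' Per-sample normalization scalars: each sample's factor is the median, over
#' genes with nonzero counts in every sample, of the ratio of that sample's
#' count to the gene's geometric mean across samples. A single-sample matrix
#' gets factor 1.
#'
#' @param counts genes x samples count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- ensure_counts(counts)
  if (ncol(counts) == 1L) {
    return(setNames(1, colnames(counts)))
  }
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    stop("no gene has nonzero counts in all samples; ",
         "supply a pseudo-reference fallback (e.g. filter samples) before normalizing")
  }
  logk <- log(counts[ok, , drop = FALSE])
  loggeo <- rowMeans(logk)
  sf <- apply(logk, 2, function(col) exp(stats::median(col - loggeo)))
  setNames(sf, colnames(counts))
}

# Gene-wise method-of-moments dispersion on normalized counts, pooled within
# conditions, shrunk toward a robustly fitted parametric mean-dispersion
# trend alpha(mu) = a0 + a1/mu. With 2(n-1) residual df per gene the raw
# moment estimator is far too noisy to plug into a Wald SE, so the gene-wise
# estimate is combined with the trend on the log scale using an
# empirical-Bayes weight derived from the spread of log residuals relative to
# the chi-square sampling variance.
estimate_dispersions <- function(Y, cond, floor = 1e-8) {
  n <- ncol(Y)
  grp <- split(seq_len(n), cond)
  mu <- rowMeans(Y)
  rss <- Reduce(`+`, lapply(grp, function(idx) {
    sub <- Y[, idx, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }))
  v <- rss / (n - length(grp))
  alpha_mom <- (v - mu) / mu^2

  # Trend fit uses every finite moment estimate, negative ones included:
  # E[(v - mu)/mu^2] = alpha even when the draw falls below zero, so
  # restricting to positive estimates would bias the trend upward (badly so
  # for near-Poisson data such as pseudo-bulk sums). Robustness comes from
  # symmetric trimming of absolute residuals, not from truncation.
  ok <- is.finite(alpha_mom) & mu > 0
  if (sum(ok) < 10L) {
    common <- if (any(ok)) max(stats::median(alpha_mom[ok]), floor) else floor
    return(rep(common, nrow(Y)))
  }
  a <- alpha_mom[ok]; m <- mu[ok]
  co <- c(stats::median(a), 0)
  for (it in 1:10) {
    fit <- stats::lm.fit(cbind(1, 1 / m), a)
    co_new <- pmax(fit$coefficients, 0)
    res <- a - (co_new[1] + co_new[2] / m)
    lim <- 4 * stats::mad(res)
    keep <- if (lim > 0) abs(res) < lim else rep(TRUE, length(res))
    if (all(keep) || sum(keep) < 10L) { co <- co_new; break }
    a <- a[keep]; m <- m[keep]
    co <- co_new
  }
  trend <- pmax(co[1] + co[2] / pmax(mu, 1e-8), floor)

  # Per-gene moderation on the log scale, active only when the trend is
  # informative (clearly above the floor); near-Poisson data gets the trend
  # outright. The empirical-Bayes weight compares the spread of log residuals
  # with the chi-square sampling variance of a 2(n-1)-df moment estimate.
  pos <- is.finite(alpha_mom) & alpha_mom > 0
  if (stats::median(trend) > 1e-4 && sum(pos) >= 10L) {
    lres <- log(alpha_mom[pos]) - log(trend[pos])
    samp_var <- trigamma((n - length(grp)) / 2)
    prior_var <- max(stats::mad(lres)^2 - samp_var, 0.25^2)
    w <- prior_var / (prior_var + samp_var)
    gene_wise <- ifelse(pos, alpha_mom, trend)
    pmax(exp(w * log(gene_wise) + (1 - w) * log(trend)), floor)
  } else {
    trend
  }
}

#' Negative-binomial Wald differential expression test
#'
#' Per-gene two-group differential expression on count data: median-of-ratios
#' normalization, a gene-wise NB dispersion shrunk toward a fitted
#' mean-dispersion trend, an NB GLM with log link fit to the normalized
#' counts, and a Wald test (two-sided normal p) on the condition coefficient.
#' p-values are Benjamini-Hochberg adjusted within the tested genes; genes
#' with zero counts in every sample are reported with `NA` p and excluded
#' from the adjustment.
#'
#' @param counts genes x samples count matrix.
#' @param sheet sample sheet data.frame with `sample_id` and `condition`
#'   columns covering the matrix columns.
#' @param contrast length-2 character vector `c(treated, control)`; the
#'   reported log2 fold change is treated over control.
#' @param model_id label stamped into the result table.
#' @return a `de_table` data.frame with columns `gene`, `base_mean`,
#'   `log2fc`, `p_value`, `p_adjusted`, `model_id`.
#' @examples
#' sim <- simulate_bulk_models(bulk_sim_config(n_models = 1, genes_total = 200,
#'                                             n_up_planted = 5, n_down_planted = 5))
#' de <- nb_wald_test(sim$models[[1]], sim$sheet, c("DTC", "control"))
#' head(de[order(de$p_value), ])
#' @export
nb_wald_test <- function(counts, sheet, contrast, model_id = "model1") {
  counts <- ensure_counts(counts)
  if (length(contrast) != 2L) stop("contrast must be c(treated, control)")
  if (!all(contrast %in% sheet$condition)) {
    stop(sprintf("contrast conditions not found in sample sheet: %s",
                 paste(setdiff(contrast, sheet$condition), collapse = ", ")))
  }
  sheet <- sheet[sheet$condition %in% contrast, , drop = FALSE]
  sheet <- sheet[sheet$sample_id %in% colnames(counts), , drop = FALSE]
  if (any(table(sheet$condition) < 2L)) {
    stop("need >=2 samples per condition for dispersion estimation")
  }
  counts <- counts[, sheet$sample_id, drop = FALSE]
  cond01 <- as.integer(sheet$condition == contrast[1L])

  sf <- size_factors(counts)
  Y <- sweep(unclass(counts), 2, sf, "/")
  nonzero <- rowSums(counts) > 0

  alpha <- rep(NA_real_, nrow(Y))
  alpha[nonzero] <- estimate_dispersions(Y[nonzero, , drop = FALSE], cond01)

  # For a saturated two-group log-link NB GLM the MLE fits the arm means of
  # the normalized counts exactly, so the condition coefficient is
  # log(mean_treated / mean_control) and the Wald SE comes from the Fisher
  # information at those means: Var = (1/mu1 + alpha)/n1 + (1/mu0 + alpha)/n0.
  # (Equality with the IRLS fit is asserted in the test suite.)
  n1 <- sum(cond01 == 1L); n0 <- sum(cond01 == 0L)
  m1 <- rowMeans(Y[, cond01 == 1L, drop = FALSE])
  m0 <- rowMeans(Y[, cond01 == 0L, drop = FALSE])
  ngene <- nrow(Y)
  log2fc <- rep(NA_real_, ngene)
  pval <- rep(NA_real_, ngene)

  ok <- nonzero & m1 > 0 & m0 > 0
  se <- sqrt((1 / m1 + alpha) / n1 + (1 / m0 + alpha) / n0)
  log2fc[ok] <- log2(m1[ok] / m0[ok])
  z <- log(m1 / m0) / se
  pval[ok] <- 2 * stats::pnorm(-abs(z[ok]))

  # degenerate arm means (one arm all-zero): pseudocount fall-back of 0.5
  deg <- nonzero & !ok
  if (any(deg)) {
    log2fc[deg] <- log2((m1[deg] + 0.5) / (m0[deg] + 0.5))
    se_pc <- sqrt((1 / (m1[deg] + 0.5) + alpha[deg]) / n1 +
                  (1 / (m0[deg] + 0.5) + alpha[deg]) / n0)
    pval[deg] <- 2 * stats::pnorm(-abs(log((m1[deg] + 0.5) / (m0[deg] + 0.5)) / se_pc))
  }
  eq <- nonzero & m1 == m0
  log2fc[eq] <- 0
  pval[eq] <- 1
  padj <- rep(NA_real_, ngene)
  tested <- !is.na(pval)
  padj[tested] <- stats::p.adjust(pval[tested], method = "BH")
  out <- data.frame(
    gene = rownames(counts),
    base_mean = rowMeans(Y),
    log2fc = log2fc,
    p_value = pval,
    p_adjusted = padj,
    model_id = model_id,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Write / read a differential-expression table
#'
#' TSV with columns gene, base_mean, log2fc, p_value, p_adjusted, model_id and
#' a one-line `#` provenance comment.
#'
#' @param de a `de_table`.
#' @param path file path.
#' @export
write_de_table <- function(de, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dtcsig DE table: model %s", de$model_id[1L]), con)
  utils::write.table(de, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene", "base_mean", "log2fc", "p_value", "p_adjusted", "model_id")
  if (!all(need %in% names(df))) {
    stop(sprintf("DE table must have columns: %s", paste(need, collapse = ", ")))
  }
  class(df) <- c("de_table", "data.frame")
  df
}
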