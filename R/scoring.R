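#' Per-cell gene-set score (UMI fraction)
#'
#' The score of cell j for a gene set is the sum of the cell's UMI over the
#' set members present in the matrix divided by the cell's total UMI, so
#' scores live in \[0, 1\], the all-genes set scores exactly 1, and scores of
#' sets partitioning the gene universe sum to exactly 1 per cell.
#'
#' @param umi genes x cells count matrix.
#' @param set character vector of gene symbols (members absent from the
#'   matrix contribute 0).
#' @param meta optional per-cell metadata data.frame with a `cell_id` column,
#'   joined onto the result.
#' @param set_name label stamped into the result.
#' @return data.frame cell_id, score, set_name (plus metadata columns).
#' @export
score_cells <- function(umi, set, meta = NULL, set_name = "set") {
  umi <- ensure_counts(umi)
  totals <- colSums(umi)
  if (any(totals == 0)) {
    stop("cells with zero total UMI cannot be scored: ",
         paste(colnames(umi)[totals == 0], collapse = ", "))
  }
  members <- rownames(umi) %in% toupper(set)
  in_set <- if (any(members)) colSums(umi[members, , drop = FALSE]) else numeric(ncol(umi))
  out <- data.frame(cell_id = colnames(umi), score = in_set / totals,
                    set_name = set_name, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    if (!"cell_id" %in% names(meta)) stop("meta must have a cell_id column")
    out <- merge(out, meta, by = "cell_id", all.x = TRUE, sort = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Per-cluster expression profile (means, z-scores, expressing fractions)
#'
#' Normalizes each cell to counts-per-10k followed by log1p, averages per
#' (gene, cluster), standardizes each gene's cluster means to z-scores
#' (population SD across clusters; all-equal means map to z = 0), and
#' reports the fraction of cells in the cluster with a nonzero raw count —
#' the numbers behind cluster heat maps and dot plots.
#'
#' @param umi genes x cells count matrix.
#' @param clusters per-cell cluster labels, named by cell id or aligned with
#'   the matrix columns.
#' @param genes optional subset of genes to profile (default: all).
#' @return a `cluster_profile` data.frame: gene, cluster, mean_expr, z,
#'   frac_expressing.
#' @export
cluster_profile <- function(umi, clusters, genes = NULL) {
  umi <- ensure_counts(umi)
  if (!is.null(names(clusters))) {
    if (!all(colnames(umi) %in% names(clusters))) {
      stop("every cell must have a cluster label")
    }
    clusters <- clusters[colnames(umi)]
  } else if (length(clusters) != ncol(umi)) {
    stop("cluster labels must cover every cell")
  }
  clusters <- as.character(clusters)
  if (anyNA(clusters)) stop("every cell must have a cluster label")
  levels <- sort(unique(clusters))
  if (length(levels) < 2L) stop("need >=2 clusters for z-scores")
  if (!is.null(genes)) {
    genes <- toupper(genes)
    missing <- setdiff(genes, rownames(umi))
    if (length(missing)) {
      warning("genes absent from matrix dropped: ", paste(missing, collapse = ", "))
    }
    umi <- umi[intersect(genes, rownames(umi)), , drop = FALSE]
    if (nrow(umi) == 0L) stop("none of the requested genes are in the matrix")
  }
  totals <- colSums(umi)
  if (any(totals == 0)) stop("cells with zero total UMI cannot be profiled")
  Y <- log1p(sweep(unclass(umi), 2, totals, "/") * 1e4)

  means <- vapply(levels, function(cl) rowMeans(Y[, clusters == cl, drop = FALSE]),
                  numeric(nrow(umi)))
  fracs <- vapply(levels, function(cl) rowMeans(umi[, clusters == cl, drop = FALSE] > 0),
                  numeric(nrow(umi)))
  if (nrow(umi) == 1L) {
    means <- matrix(means, nrow = 1, dimnames = list(rownames(umi), levels))
    fracs <- matrix(fracs, nrow = 1, dimnames = list(rownames(umi), levels))
  }
  z <- t(apply(means, 1, function(x) {
    s <- pop_sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  out <- data.frame(
    gene = rep(rownames(umi), times = length(levels)),
    cluster = rep(levels, each = nrow(umi)),
    mean_expr = as.vector(means),
    z = as.vector(z),
    frac_expressing = as.vector(fracs),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cluster_profile", "data.frame")
  out
}

#' Associate genes with a phenotype via a reference gene
#'
#' Correlates every gene's per-cluster mean expression vector with that of a
#' phenotype reference gene (e.g. AGER for AT1, SERPINE1 for mesenchymal,
#' BPIFB1 for mucous/serous). Genes with Pearson r above `r_threshold` are
#' flagged as representative of the phenotype; the p-value is the two-sided
#' simple-linear-regression (equivalently correlation-test) p.
#'
#' @param profile a `cluster_profile` from [cluster_profile()].
#' @param reference_gene symbol of the reference gene (must be profiled).
#' @param r_threshold selection threshold on r (default 0.9).
#' @return data.frame gene, reference_gene, pearson_r, p_value, selected.
#' @export
associate_with_reference <- function(profile, reference_gene, r_threshold = 0.9) {
  stopifnot(inherits(profile, "cluster_profile"))
  reference_gene <- toupper(reference_gene)
  gs <- sort(unique(profile$gene))
  cs <- sort(unique(profile$cluster))
  wide <- matrix(NA_real_, length(gs), length(cs), dimnames = list(gs, cs))
  wide[cbind(match(profile$gene, gs), match(profile$cluster, cs))] <- profile$mean_expr
  if (!reference_gene %in% rownames(wide)) {
    stop(sprintf("reference gene '%s' not present in the profile", reference_gene))
  }
  n_cl <- ncol(wide)
  if (n_cl < 3L) stop("need >=3 clusters for a correlation p-value")
  ref <- wide[reference_gene, ]
  if (stats::sd(ref) == 0) {
    stop(sprintf("reference gene '%s' has zero variance across clusters", reference_gene))
  }
  r <- apply(wide, 1, function(x) {
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, ref)
  })
  df <- n_cl - 2L
  tstat <- r * sqrt(df / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[is.infinite(tstat)] <- 0
  out <- data.frame(
    gene = rownames(wide),
    reference_gene = reference_gene,
    pearson_r = unname(r),
    p_value = unname(p),
    selected = !is.na(r) & r > r_threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
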