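#' Configuration for the multi-model bulk RNA-seq simulator
#'
#' Defaults mirror the study design the pipeline targets: seven independent
#' treated-vs-untreated models with three replicates per arm, a shared program
#' of 212 up- and 495 down-regulated genes planted at |log2FC| = 1.5, and
#' negative-binomial counts with dispersion 0.1.
#'
#' @param n_models number of independent models (datasets).
#' @param genes_total size of the simulated gene universe.
#' @param n_up_planted,n_down_planted numbers of genes carrying the shared
#'   up/down program.
#' @param effect_log2fc planted |log2 fold change| (treated vs control).
#' @param dropout_models_per_gene number of models (0 or 1) in which each
#'   planted gene carries no effect; which models are masked is drawn
#'   uniformly per gene. Default 0: sub-maximal cross-model support then
#'   arises from sampling noise alone.
#' @param samples_per_condition replicates per arm in every model.
#' @param nb_dispersion negative-binomial dispersion alpha (variance
#'   mu + alpha mu^2).
#' @param library_size_mean expected per-sample sequencing depth.
#' @param baseline_sdlog log-normal spread of baseline gene abundances.
#' @param seed integer seed; identical seeds give identical output.
#' @return a `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_models = 7, genes_total = 5000,
                            n_up_planted = 212, n_down_planted = 495,
                            effect_log2fc = 1.5,
                            dropout_models_per_gene = 0,
                            samples_per_condition = 3,
                            nb_dispersion = 0.1,
                            library_size_mean = 2e7,
                            baseline_sdlog = 1,
                            seed = 1) {
  cfg <- list(n_models = n_models, genes_total = genes_total,
              n_up_planted = n_up_planted, n_down_planted = n_down_planted,
              effect_log2fc = effect_log2fc,
              dropout_models_per_gene = dropout_models_per_gene,
              samples_per_condition = samples_per_condition,
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              baseline_sdlog = baseline_sdlog, seed = seed)
  if (cfg$n_up_planted + cfg$n_down_planted >= cfg$genes_total) {
    stop("planted genes must number fewer than genes_total")
  }
  if (cfg$dropout_models_per_gene >= cfg$n_models) {
    stop("dropout_models_per_gene must be smaller than n_models")
  }
  if (!cfg$dropout_models_per_gene %in% c(0, 1)) {
    stop("dropout_models_per_gene must be 0 or 1")
  }
  if (cfg$samples_per_condition < 2) stop("need >=2 samples per condition")
  stopifnot_scalar_number(cfg$nb_dispersion, "nb_dispersion", 0)
  stopifnot_scalar_number(cfg$effect_log2fc, "effect_log2fc", 0)
  class(cfg) <- "bulk_sim_config"
  cfg
}

#' Simulate treated-vs-untreated bulk counts for several models
#'
#' Each model draws its own log-normal baseline abundance per gene; counts are
#' negative-binomial around library-size-scaled expected proportions. Planted
#' genes have their treated-arm mean multiplied by `2^(+-effect_log2fc)`
#' except in their (optional) masked dropout models. Returns the per-model
#' count matrices, a combined sample sheet, and the planted ground truth.
#'
#' @param cfg a [bulk_sim_config()].
#' @return list with elements `models` (named list of `count_matrix`),
#'   `sheet` (sample sheet data.frame), and `truth` (list with `planted_up`,
#'   `planted_down`, `dropout` — named list mapping planted gene to masked
#'   model ids).
#' @export
simulate_bulk_models <- function(cfg = bulk_sim_config()) {
  stopifnot(inherits(cfg, "bulk_sim_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("G%05d", seq_len(cfg$genes_total))
    planted_idx <- sample.int(cfg$genes_total, cfg$n_up_planted + cfg$n_down_planted)
    up <- sort(genes[planted_idx[seq_len(cfg$n_up_planted)]])
    down <- sort(genes[planted_idx[cfg$n_up_planted + seq_len(cfg$n_down_planted)]])
    lfc <- setNames(numeric(cfg$genes_total), genes)
    lfc[up] <- cfg$effect_log2fc
    lfc[down] <- -cfg$effect_log2fc

    model_ids <- sprintf("model%d", seq_len(cfg$n_models))
    dropout <- list()
    if (cfg$dropout_models_per_gene > 0) {
      for (g in c(up, down)) {
        dropout[[g]] <- sample(model_ids, cfg$dropout_models_per_gene)
      }
    }

    n <- cfg$samples_per_condition
    sheets <- list()
    models <- list()
    for (m in model_ids) {
      base <- stats::rlnorm(cfg$genes_total, meanlog = 0, sdlog = cfg$baseline_sdlog)
      names(base) <- genes
      fold <- 2^lfc
      if (length(dropout)) {
        masked <- names(dropout)[vapply(dropout, function(d) m %in% d, logical(1))]
        fold[masked] <- 1
      }
      prop_ctrl <- base / sum(base)
      prop_trt <- base * fold / sum(base)   # composition shift deliberately ignored
      libs <- stats::rlnorm(2 * n, meanlog = log(cfg$library_size_mean), sdlog = 0.1)
      mu <- cbind(outer(prop_ctrl, libs[seq_len(n)]),
                  outer(prop_trt, libs[n + seq_len(n)]))
      counts <- matrix(
        stats::rnbinom(length(mu), mu = mu, size = 1 / max(cfg$nb_dispersion, 1e-12)),
        nrow = cfg$genes_total
      )
      sample_ids <- paste0(m, "_", rep(c("control", "DTC"), each = n), seq_len(n))
      dimnames(counts) <- list(genes, sample_ids)
      models[[m]] <- as_count_matrix(counts)
      sheets[[m]] <- data.frame(
        sample_id = sample_ids, model_id = m,
        condition = rep(c("control", "DTC"), each = n),
        stringsAsFactors = FALSE
      )
    }
    list(
      models = models,
      sheet = do.call(rbind, c(sheets, list(make.row.names = FALSE))),
      truth = list(planted_up = up, planted_down = down, dropout = dropout)
    )
  })
}

#' Configuration for the clustered single-cell UMI simulator
#'
#' Emulates a single-cell dataset partitioned into phenotypic clusters
#' (e.g. mucous/serous, AT1-like, mesenchymal, cycling), where each cluster
#' overexpresses its marker genes by a fold factor on the multinomial
#' probability scale.
#'
#' @param cluster_spec list of lists with fields `name`, `n_cells`,
#'   `markers` (character vector, possibly empty), `marker_fold`.
#' @param n_background_genes number of unnamed background genes added to the
#'   union of all marker genes to form the gene universe.
#' @param umi_per_cell_mean Poisson mean of per-cell total UMI.
#' @param condition optional per-cluster condition labels (defaults to
#'   `"all"` for every cluster).
#' @param seed integer seed.
#' @return an `sc_sim_config` list.
#' @export
sc_sim_config <- function(cluster_spec, n_background_genes = 500,
                          umi_per_cell_mean = 5000, condition = NULL,
                          seed = 1) {
  nm <- vapply(cluster_spec, function(cl) cl$name, character(1))
  if (anyDuplicated(nm)) stop("cluster names must be unique")
  ncl <- vapply(cluster_spec, function(cl) cl$n_cells, numeric(1))
  if (any(ncl < 1)) stop("each cluster needs n_cells >= 1")
  if (is.null(condition)) condition <- setNames(rep("all", length(nm)), nm)
  cfg <- list(cluster_spec = cluster_spec,
              n_background_genes = n_background_genes,
              umi_per_cell_mean = umi_per_cell_mean,
              condition = condition, seed = seed)
  class(cfg) <- "sc_sim_config"
  cfg
}

#' Simulate a clustered single-cell UMI matrix
#'
#' Per cell, the total UMI count is Poisson around `umi_per_cell_mean` and
#' gene counts are multinomial over a shared baseline probability vector in
#' which the cell's cluster markers have their probability mass multiplied by
#' `marker_fold` (then renormalized).
#'
#' @param cfg an [sc_sim_config()].
#' @return list with `counts` (genes x cells `count_matrix`), `meta`
#'   (data.frame cell_id, cluster, condition), `truth` (cluster labels and the
#'   per-cluster gene probability vectors used), and `totals` (the drawn
#'   per-cell totals).
#' @export
simulate_sc <- function(cfg) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  with_seed(cfg$seed, {
    markers <- unique(toupper(unlist(lapply(cfg$cluster_spec, `[[`, "markers"))))
    genes <- c(markers, sprintf("BG%04d", seq_len(cfg$n_background_genes)))
    base <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 1)
    names(base) <- genes

    probs <- list()
    for (cl in cfg$cluster_spec) {
      w <- base
      if (length(cl$markers)) w[toupper(cl$markers)] <- w[toupper(cl$markers)] * cl$marker_fold
      probs[[cl$name]] <- w / sum(w)
    }

    n_cells <- vapply(cfg$cluster_spec, function(cl) cl$n_cells, numeric(1))
    total_cells <- sum(n_cells)
    cell_ids <- sprintf("cell%05d", seq_len(total_cells))
    cluster <- rep(vapply(cfg$cluster_spec, `[[`, character(1), "name"), times = n_cells)

    totals <- stats::rpois(total_cells, cfg$umi_per_cell_mean)
    totals[totals == 0L] <- 1L   # keep every cell scoreable
    counts <- matrix(0, nrow = length(genes), ncol = total_cells,
                     dimnames = list(genes, cell_ids))
    for (j in seq_len(total_cells)) {
      counts[, j] <- stats::rmultinom(1L, size = totals[j], prob = probs[[cluster[j]]])
    }
    meta <- data.frame(
      cell_id = cell_ids, cluster = cluster,
      condition = unname(cfg$condition[cluster]),
      stringsAsFactors = FALSE
    )
    list(counts = as_count_matrix(counts), meta = meta,
         truth = list(cluster = setNames(cluster, cell_ids), probs = probs),
         totals = setNames(totals, cell_ids))
  })
}

#' Configuration for the FUCCI track simulator
#'
#' Each simulated cell starts in G1 (red reporter high), enters S/G2 (green
#' high) after an exponential G1 dwell, and then realizes one planted fate:
#' mitosis (a division event ends the track), endoreplication (return to a
#' G1-like state without division), or death before dividing. Intensities are
#' on a 0-1000 arbitrary-unit scale with logistic transitions between phases
#' and optional Gaussian channel noise.
#'
#' @param n_cells_per_condition tracked cells (default 20, the study's
#'   per-condition tracking depth).
#' @param fate_probs numeric triple (p_mitosis, p_endoreplication, p_death)
#'   summing to 1.
#' @param phase_duration_means_h named list with mean G1 and S/G2 dwell
#'   times in hours.
#' @param channel_noise_sd Gaussian noise SD added to both channels
#'   (intensity units; 0 gives noiseless tracks).
#' @param sampling_interval_h imaging interval in hours.
#' @param t_end_h observation window in hours.
#' @param condition condition label stamped into cell ids.
#' @param seed integer seed.
#' @return a `track_sim_config` list.
#' @export
track_sim_config <- function(n_cells_per_condition = 20,
                             fate_probs = c(mitosis = 0.5,
                                            endoreplication = 0.25,
                                            death = 0.25),
                             phase_duration_means_h = list(G1 = 20, SG2 = 12),
                             channel_noise_sd = 0,
                             sampling_interval_h = 1,
                             t_end_h = 72,
                             condition = "cond1",
                             seed = 1) {
  if (abs(sum(fate_probs) - 1) > 1e-9) stop("fate probabilities must sum to 1")
  if (length(fate_probs) != 3L) stop("fate_probs must be (mitosis, endoreplication, death)")
  if (any(unlist(phase_duration_means_h) <= 0)) stop("phase durations must be positive")
  cfg <- list(n_cells_per_condition = n_cells_per_condition,
              fate_probs = fate_probs,
              phase_duration_means_h = phase_duration_means_h,
              channel_noise_sd = channel_noise_sd,
              sampling_interval_h = sampling_interval_h,
              t_end_h = t_end_h, condition = condition, seed = seed)
  class(cfg) <- "track_sim_config"
  cfg
}

# logistic pulse: intensity moving from `from` to `to` centered at t0,
# ~1 h transition scale
logistic_level <- function(t, t0, from, to, scale = 0.5) {
  from + (to - from) / (1 + exp(-(t - t0) / scale))
}

#' Simulate FUCCI reporter tracks with planted fates
#'
#' @param cfg a [track_sim_config()].
#' @return list with `tracks` (a `track_table`) and `truth` (data.frame
#'   cell_id, condition, fate, t_SG2_entry, and per-timepoint true phase in
#'   attribute-free long form under `phases`).
#' @export
simulate_tracks <- function(cfg = track_sim_config()) {
  stopifnot(inherits(cfg, "track_sim_config"))
  HI <- 800; LO <- 30
  with_seed(cfg$seed, {
    n <- cfg$n_cells_per_condition
    fates <- sample(c("mitosis", "endoreplication", "death"), n, replace = TRUE,
                    prob = cfg$fate_probs)
    times <- seq(0, cfg$t_end_h, by = cfg$sampling_interval_h)
    rows <- list()
    truth_rows <- list()
    phase_rows <- list()
    for (i in seq_len(n)) {
      cid <- sprintf("%s_cell%03d", cfg$condition, i)
      # dwell floors: S/G2+M shorter than ~5 h is not biologically plausible
      # and would be invisible at 1 h sampling
      g1_d <- pmax(stats::rexp(1, 1 / cfg$phase_duration_means_h$G1), 2)
      sg2_d <- pmax(stats::rexp(1, 1 / cfg$phase_duration_means_h$SG2), 5)
      # every simulated cell completes its fate inside the observation window
      t_entry <- min(g1_d, cfg$t_end_h - 8)
      t_exit <- min(t_entry + sg2_d, cfg$t_end_h - 1)
      fate <- fates[i]

      red <- logistic_level(times, t_entry, HI, LO)
      green <- logistic_level(times, t_entry, LO, HI)
      divided <- numeric(length(times))
      dead <- numeric(length(times))
      keep <- rep(TRUE, length(times))
      true_phase <- ifelse(times < t_entry, "G1", "S/G2")

      if (fate == "mitosis") {
        idx <- which(times >= t_exit)[1L]
        divided[idx] <- 1
        keep <- times <= times[idx]          # offspring not tracked
      } else if (fate == "endoreplication") {
        red <- red + logistic_level(times, t_exit, 0, HI - LO)
        green <- green - logistic_level(times, t_exit, 0, HI - LO)
        true_phase[times >= t_exit] <- "G1"
      } else { # death during S/G2, before any division
        idx <- which(times >= t_exit)[1L]
        dead[times >= times[idx]] <- 1
        decay <- times >= times[idx]
        red[decay] <- 0
        green[decay] <- 0
        true_phase[decay] <- "dead"
        keep <- times <= times[idx] + 3      # a few confirmatory dead frames
      }
      if (cfg$channel_noise_sd > 0) {
        red <- red + stats::rnorm(length(red), 0, cfg$channel_noise_sd)
        green <- green + stats::rnorm(length(green), 0, cfg$channel_noise_sd)
      }
      red <- pmax(red, 0); green <- pmax(green, 0)
      rows[[i]] <- data.frame(
        cell_id = cid, time_h = times[keep], red = red[keep],
        green = green[keep], divided = divided[keep], dead = dead[keep],
        stringsAsFactors = FALSE
      )
      truth_rows[[i]] <- data.frame(
        cell_id = cid, condition = cfg$condition, fate = fate,
        t_SG2_entry = t_entry, stringsAsFactors = FALSE
      )
      phase_rows[[i]] <- data.frame(
        cell_id = cid, time_h = times[keep], phase = true_phase[keep],
        stringsAsFactors = FALSE
      )
    }
    list(
      tracks = as_track_table(do.call(rbind, rows)),
      truth = list(
        fates = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
        phases = do.call(rbind, c(phase_rows, list(make.row.names = FALSE)))
      )
    )
  })
}
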