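test_that("all three generators are deterministic given a seed", {
  cfgb <- bulk_sim_config(n_models = 2, genes_total = 100, n_up_planted = 5,
                          n_down_planted = 5, library_size_mean = 1e5, seed = 7)
  a <- simulate_bulk_models(cfgb)
  b <- simulate_bulk_models(cfgb)
  expect_identical(a, b)

  cfgs <- sc_sim_config(list(list(name = "A", n_cells = 10, markers = "AGER",
                                  marker_fold = 5)),
                        n_background_genes = 30, umi_per_cell_mean = 200, seed = 3)
  expect_identical(simulate_sc(cfgs), simulate_sc(cfgs))

  cfgt <- track_sim_config(n_cells_per_condition = 5, channel_noise_sd = 20, seed = 9)
  expect_identical(simulate_tracks(cfgt), simulate_tracks(cfgt))

  # a different seed changes the draws
  cfgb2 <- cfgb; cfgb2$seed <- 8
  expect_false(identical(simulate_bulk_models(cfgb2)$models, a$models))
})

test_that("bulk simulator plants the configured effect and truth lists", {
  none <- simulate_bulk_models(bulk_sim_config(
    n_models = 2, genes_total = 80, n_up_planted = 0, n_down_planted = 0,
    library_size_mean = 1e5))
  expect_length(none$truth$planted_up, 0)
  expect_length(none$truth$planted_down, 0)

  # empirical mean log2 ratio of planted genes ~= effect at large n
  cfg <- bulk_sim_config(n_models = 1, genes_total = 400, n_up_planted = 40,
                         n_down_planted = 40, effect_log2fc = 1.5,
                         samples_per_condition = 60, library_size_mean = 2e6,
                         seed = 11)
  sim <- simulate_bulk_models(cfg)
  cm <- sim$models[[1]]
  trt <- sim$sheet$sample_id[sim$sheet$condition == "DTC"]
  ctl <- sim$sheet$sample_id[sim$sheet$condition == "control"]
  ratio <- log2(rowMeans(cm[, trt]) / rowMeans(cm[, ctl]))
  expect_equal(mean(ratio[sim$truth$planted_up]), 1.5, tolerance = 0.05)
  expect_equal(mean(ratio[sim$truth$planted_down]), -1.5, tolerance = 0.05)
  expect_length(intersect(sim$truth$planted_up, sim$truth$planted_down), 0)

  # dropout masks the effect in the assigned model
  cfgd <- bulk_sim_config(n_models = 3, genes_total = 300, n_up_planted = 30,
                          n_down_planted = 0, effect_log2fc = 2,
                          dropout_models_per_gene = 1,
                          samples_per_condition = 30, library_size_mean = 1e6,
                          seed = 5)
  simd <- simulate_bulk_models(cfgd)
  g <- simd$truth$planted_up[1]
  masked <- simd$truth$dropout[[g]]
  for (m in names(simd$models)) {
    cmn <- simd$models[[m]]
    sh <- simd$sheet[simd$sheet$model_id == m, ]
    r <- log2(mean(cmn[g, sh$sample_id[sh$condition == "DTC"]]) /
              mean(cmn[g, sh$sample_id[sh$condition == "control"]]))
    if (m %in% masked) expect_lt(abs(r), 1) else expect_gt(r, 1)
  }
})

test_that("single-cell simulator respects cluster structure and conservation", {
  cfg <- sc_sim_config(
    cluster_spec = list(
      list(name = "AT1", n_cells = 150, markers = c("AGER", "PDPN"), marker_fold = 10),
      list(name = "mes", n_cells = 150, markers = c("SERPINE1"), marker_fold = 10)
    ),
    n_background_genes = 100, umi_per_cell_mean = 1000, seed = 2
  )
  sim <- simulate_sc(cfg)
  expect_equal(ncol(sim$counts), 300)
  # conservation: per-cell column sums equal the drawn totals exactly
  expect_equal(unname(colSums(sim$counts)), unname(sim$totals[colnames(sim$counts)]))

  # closed-form multinomial expectation: mean AGER proportion in AT1 matches
  # the generator's probability vector and exceeds the other cluster
  at1 <- sim$meta$cell_id[sim$meta$cluster == "AT1"]
  mes <- sim$meta$cell_id[sim$meta$cluster == "mes"]
  prop_at1 <- mean(sim$counts["AGER", at1] / colSums(sim$counts[, at1]))
  prop_mes <- mean(sim$counts["AGER", mes] / colSums(sim$counts[, mes]))
  expect_equal(prop_at1, sim$truth$probs$AT1[["AGER"]], tolerance = 0.1)
  expect_gt(prop_at1, prop_mes)

  # single cluster, no markers: per-gene mean proportions match the shared
  # baseline probabilities (exchangeability up to the drawn baseline)
  cfg1 <- sc_sim_config(list(list(name = "only", n_cells = 200, markers = character(0),
                                  marker_fold = 1)),
                        n_background_genes = 50, umi_per_cell_mean = 2000, seed = 4)
  sim1 <- simulate_sc(cfg1)
  emp <- rowMeans(sweep(unclass(sim1$counts), 2, colSums(sim1$counts), "/"))
  expect_equal(unname(emp), unname(sim1$truth$probs$only[rownames(sim1$counts)]),
               tolerance = 0.05)
})

test_that("track simulator realizes planted fates", {
  allmit <- simulate_tracks(track_sim_config(
    n_cells_per_condition = 15, fate_probs = c(1, 0, 0), channel_noise_sd = 0, seed = 1))
  div_per_cell <- tapply(allmit$tracks$divided, allmit$tracks$cell_id, sum)
  expect_true(all(div_per_cell == 1))
  expect_true(all(allmit$tracks$dead == 0))

  alldie <- simulate_tracks(track_sim_config(
    n_cells_per_condition = 15, fate_probs = c(0, 0, 1), channel_noise_sd = 0, seed = 1))
  last_dead <- tapply(alldie$tracks$dead, alldie$tracks$cell_id, function(x) x[length(x)])
  expect_true(all(last_dead == 1))
  expect_true(all(alldie$tracks$divided == 0))

  # empirical fate frequencies within 3 binomial SDs of planted
  p <- c(0.5, 0.25, 0.25)
  simf <- simulate_tracks(track_sim_config(
    n_cells_per_condition = 400, fate_probs = p, channel_noise_sd = 0, seed = 6))
  freq <- table(factor(simf$truth$fates$fate,
                       levels = c("mitosis", "endoreplication", "death"))) / 400
  for (i in 1:3) {
    expect_lt(abs(freq[[i]] - p[i]), 3 * sqrt(p[i] * (1 - p[i]) / 400))
  }
})

test_that("with no planted genes the downstream DE p-values are uniform", {
  # at 15 replicates per arm the Wald normal approximation is accurate and
  # any formula error in the test statistic would break KS uniformity
  sim <- simulate_bulk_models(bulk_sim_config(
    n_models = 1, genes_total = 5000, n_up_planted = 0, n_down_planted = 0,
    samples_per_condition = 15, seed = 31))
  de <- nb_wald_test(sim$models[[1]], sim$sheet, c("DTC", "control"))
  ks <- suppressWarnings(stats::ks.test(de$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)

  # at the study's 3 + 3 design the tail calibration stays close to nominal
  # (the normal approximation leaves a small liberal bias at this depth)
  sim3 <- simulate_bulk_models(bulk_sim_config(
    n_models = 1, genes_total = 5000, n_up_planted = 0, n_down_planted = 0, seed = 31))
  de3 <- nb_wald_test(sim3$models[[1]], sim3$sheet, c("DTC", "control"))
  expect_lt(abs(mean(de3$p_value < 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(de3$p_value < 0.01) - 0.01), 0.01)
})
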