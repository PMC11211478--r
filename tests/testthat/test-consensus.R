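# seven toy models where gene support is fully controlled
toy_tables <- function(n_models = 7) {
  genes <- c("ALL7", "FIVE", "SIX", "DOWN7", "NULL1", "NULL2")
  lapply(seq_len(n_models), function(m) {
    lfc <- c(2, if (m <= 5) 2 else 0, if (m <= 6) 1 else 0, -1.5, 0.1, -0.05)
    p <- c(1e-5, if (m <= 5) 1e-4 else 0.5, if (m <= 6) 1e-3 else 0.9,
           1e-6, 0.3, 0.8)
    make_de(genes, lfc, p, model_id = paste0("m", m))
  })
}

test_that("the m-of-n rule admits and excludes genes at the support boundary", {
  sig <- build_consensus(toy_tables(), alpha = 0.01, lfc_threshold = 0.5,
                         min_support = 6)
  expect_setequal(sig$up$gene, c("ALL7", "SIX"))
  expect_equal(sig$up$support[sig$up$gene == "ALL7"], 7)
  expect_equal(sig$up$support[sig$up$gene == "SIX"], 6)
  expect_false("FIVE" %in% sig$up$gene)   # 5/7 < 6
  expect_equal(sig$down$gene, "DOWN7")
  # mean over all models, supporting or not: SIX has lfc 1 in 6 models, 0 in 1
  expect_equal(sig$up$mean_log2fc[sig$up$gene == "SIX"], 6 / 7)
  expect_length(intersect(sig$up$gene, sig$down$gene), 0)
})

test_that("consensus validates inputs", {
  expect_error(build_consensus(toy_tables()[1:2], min_support = 3), "min_support")
  expect_error(build_consensus(toy_tables()[1], min_support = 1), "at least 2")
})

test_that("genes absent from a model count as non-supporting", {
  tabs <- toy_tables()
  tabs[[7]] <- tabs[[7]][tabs[[7]]$gene != "ALL7", ]  # drop ALL7 from model 7
  sig_int <- build_consensus(tabs, min_support = 6, universe = "intersection")
  expect_false("ALL7" %in% sig_int$up$gene)           # not in intersection universe
  sig_uni <- build_consensus(tabs, min_support = 6, universe = "union")
  expect_true("ALL7" %in% sig_uni$up$gene)            # 6/7 support still suffices
  expect_equal(sig_uni$up$support[sig_uni$up$gene == "ALL7"], 6)
})

test_that("ranking by mean log2FC is a descending sort with lexicographic ties", {
  sig <- build_consensus(toy_tables(), min_support = 6)
  rk <- rank_by_mean_lfc(sig)
  expect_equal(rk$gene[1], "ALL7")
  ord <- order(-rk$mean_log2fc, rk$gene)
  expect_equal(ord, seq_len(nrow(rk)))

  # independent sort oracle on a randomized signature
  set.seed(3)
  genes <- sprintf("R%02d", 1:20)
  lfc <- round(rnorm(20), 1)  # creates ties
  tabs <- lapply(1:2, function(m) make_de(genes, lfc, rep(1e-4, 20), paste0("m", m)))
  sig2 <- build_consensus(tabs, min_support = 2, lfc_threshold = -10)
  rk2 <- rank_by_mean_lfc(sig2)
  oracle <- genes[order(-lfc, genes)]
  expect_equal(rk2$gene[rk2$direction == "up"],
               oracle[oracle %in% rk2$gene[rk2$direction == "up"]])
})

test_that("tightening any threshold never enlarges the signature", {
  set.seed(41)
  genes <- sprintf("G%03d", 1:150)
  tabs <- lapply(1:7, function(m) {
    make_de(genes, rnorm(150, 0, 1.2), runif(150)^2, paste0("m", m))
  })
  base <- build_consensus(tabs, alpha = 0.05, lfc_threshold = 0.3, min_support = 4)
  for (variant in list(
    build_consensus(tabs, alpha = 0.01, lfc_threshold = 0.3, min_support = 4),
    build_consensus(tabs, alpha = 0.05, lfc_threshold = 0.8, min_support = 4),
    build_consensus(tabs, alpha = 0.05, lfc_threshold = 0.3, min_support = 6)
  )) {
    expect_true(all(variant$up$gene %in% base$up$gene))
    expect_true(all(variant$down$gene %in% base$down$gene))
  }
  expect_length(intersect(base$up$gene, base$down$gene), 0)
})

test_that("cohort overlap counts signature genes meeting the cohort criterion", {
  sig <- build_consensus(toy_tables(), min_support = 6)  # up: ALL7, SIX
  cohort <- make_de(c("ALL7", "SIX", "OTHER"), c(1.2, 0.1, 3), c(1e-4, 0.5, 1e-6),
                    "cohort")
  rep <- overlap_with_cohort(sig, cohort, "up")
  expect_equal(rep$n_signature, 2)
  expect_equal(rep$n_overlap, 1)
  expect_equal(rep$percent_overlap, 50)
  expect_equal(rep$overlapping_genes, "ALL7")

  # genes missing from the cohort are non-overlapping but reported
  cohort2 <- make_de("ALL7", 1.2, 1e-4, "cohort")
  rep2 <- overlap_with_cohort(sig, cohort2, "up")
  expect_equal(rep2$missing_genes, "SIX")
  expect_equal(rep2$percent_overlap, 50)

  # self-consistency: with min_support = n_models each contributing model
  # reproduces the signature fully
  sig7 <- build_consensus(toy_tables(), min_support = 7)
  rep3 <- overlap_with_cohort(sig7, toy_tables()[[1]], "up")
  expect_equal(rep3$percent_overlap, 100)

  # a signature with no down genes rejects a down-overlap request
  up_only <- build_consensus(
    lapply(1:2, function(m) make_de(c("A", "B"), c(2, 2), c(1e-5, 1e-5), paste0("m", m))),
    min_support = 2)
  expect_error(overlap_with_cohort(up_only, cohort, "down"), "empty signature")
})

test_that("a 4-gene signature with 3 cohort hits reports 75 percent", {
  genes <- c("A", "B", "C", "D")
  tabs <- lapply(1:2, function(m) make_de(genes, rep(2, 4), rep(1e-5, 4), paste0("m", m)))
  sig <- build_consensus(tabs, min_support = 2)
  cohort <- make_de(genes, c(2, 2, 2, 0), c(1e-4, 1e-4, 1e-4, 1e-4), "cohort")
  rep <- overlap_with_cohort(sig, cohort, "up")
  expect_equal(rep$n_overlap, 3)
  expect_equal(rep$percent_overlap, 75)
})

test_that("shuffled condition labels yield an (almost) empty consensus", {
  sim <- simulate_bulk_models(bulk_sim_config(
    n_models = 7, genes_total = 2000, n_up_planted = 80, n_down_planted = 80,
    library_size_mean = 2e6, seed = 47))
  tabs <- lapply(names(sim$models), function(m) {
    sh <- sim$sheet[sim$sheet$model_id == m, ]
    sh$condition <- with_seed_shuffle(sh$condition, seed = match(m, names(sim$models)))
    nb_wald_test(sim$models[[m]], sh, c("DTC", "control"), model_id = m)
  })
  sig <- build_consensus(tabs, alpha = 0.01, lfc_threshold = 0.5, min_support = 6)
  expect_lte(nrow(sig$up) + nrow(sig$down), 2)
})

test_that("signatures export to GMT with a support TSV companion", {
  sig <- build_consensus(toy_tables(), min_support = 6)
  f <- file.path(withr_local_tempdir(), "sig.gmt")
  write_signature(sig, f)
  gs <- read_gmt(f)
  expect_setequal(gs$DTC_UP, sig$up$gene)
  expect_setequal(gs$DTC_DOWN, sig$down$gene)
  expect_true(file.exists(sub("\\.gmt$", ".tsv", f)))
})
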