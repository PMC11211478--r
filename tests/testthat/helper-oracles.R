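# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from their definitions, not from package internals.

# Benjamini-Hochberg step-up from the definition: adj_i = min over j with
# p_(j) >= p_(i) of p_(j) * n / j, capped at 1.
bh_brute <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(pmin(ranked[i:n] * n / (i:n), 1))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Full explicit running-sum enrichment score.
es_brute <- function(ranked, set, weight_p = 1) {
  hit <- names(ranked) %in% set
  stopifnot(any(hit))
  w <- abs(ranked)^weight_p
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- if (sum(!hit) > 0) 1 / sum(!hit) else 0
  run <- cumsum(ifelse(hit, inc, -dec))
  if (max(run) >= -min(run)) max(run) else min(run)
}

# TRUE when the running sum's positive and negative extrema tie in magnitude,
# making the signed extremum convention-dependent
es_extremum_tied <- function(ranked, set, weight_p = 1) {
  hit <- names(ranked) %in% set
  w <- abs(ranked)^weight_p
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- if (sum(!hit) > 0) 1 / sum(!hit) else 0
  run <- cumsum(ifelse(hit, inc, -dec))
  abs(max(run) + min(run)) < 1e-12 && min(run) < 0
}

with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  sample(x)
}

withr_local_tempfile <- function(env = parent.frame()) {
  withr::local_tempfile(.local_envir = env)
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# Tiny genes x samples count fixture.
tiny_counts <- function() {
  m <- matrix(c(1, 2, 0, 5, 3, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("TP53", "EGFR", "AXL"), c("s1", "s2")))
  as_count_matrix(m)
}

# Hand-built DE table.
make_de <- function(genes, lfc, p, model_id = "m1") {
  structure(
    data.frame(gene = genes, base_mean = 10, log2fc = lfc, p_value = p,
               p_adjusted = stats::p.adjust(p, "BH"), model_id = model_id,
               stringsAsFactors = FALSE),
    class = c("de_table", "data.frame")
  )
}

# Balanced two-condition sample sheet for one model.
make_sheet <- function(samples, conditions, model_id = "m1") {
  data.frame(sample_id = samples, model_id = model_id, condition = conditions,
             stringsAsFactors = FALSE)
}
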