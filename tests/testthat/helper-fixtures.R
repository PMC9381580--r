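# Shared fixtures and independent oracles used across the suite.

# A tiny deterministic expression matrix.
tiny_matrix <- function() {
  expression_matrix(matrix(c(5, 2, 3, 4, 1, 6), nrow = 3,
                           dimnames = list(NULL, c("A", "B"))),
                    probe_ids = c("p1", "p2", "p3"),
                    gene_symbols = c("g1", "g2", "g3"),
                    sample_ids = c("A", "B"))
}

# Matrix carrying the 21-gene signature with supplied values.
signature_matrix <- function(values, sample_ids = paste0("s", seq_len(ncol(values)))) {
  sig <- signature_21()
  expression_matrix(values, sig$probe_id, sig$gene_symbol, sample_ids)
}

# Brute-force oracle for the threshold-sweep metrics: enumerate every
# threshold, keep the best TPR among thresholds with zero FPR, and count
# positive-negative score pairs for the AUC.
brute_force_metrics <- function(scores, labels) {
  pos <- labels == "positive"
  sens0 <- 0
  for (thr in unique(scores)) {
    if (!any(scores[!pos] > thr)) sens0 <- max(sens0, mean(scores[pos] > thr))
  }
  sp <- scores[pos]; sn <- scores[!pos]
  cnt <- 0
  for (a in sp) cnt <- cnt + sum(a > sn) + 0.5 * sum(a == sn)
  list(sens0 = sens0, auc = cnt / (length(sp) * length(sn)))
}

# A small perfectly separable extreme-response bundle: the first `n_inf`
# genes are shifted by `effect` in positives.
toy_bundle <- function(n_pos = 8, n_neg = 8, n_genes = 20, n_inf = 4,
                       effect = 3, seed = 1) {
  generate_cohort(sim_config(n_genes = n_genes, n_informative = n_inf,
                             n_positive = n_pos, n_negative = n_neg,
                             effect_size = effect, noise_sd = 1, seed = seed))
}

# A compact discovery experiment (synthetic discovery cohort + one
# batch-shifted external cohort) used by the workflow and leakage tests.
small_experiment <- function(out_dir = NULL, perm_validation_labels = FALSE,
                             seed = 71) {
  disc <- generate_cohort(sim_config(n_genes = 120, n_informative = 6,
                                     effect_size = 2.5, seed = seed))
  vcfg <- sim_config(n_genes = 120, n_informative = 6, effect_size = 2.5,
                     n_positive = 6, n_negative = 10, batch_shift = 2,
                     cohort_label = "ext", seed = seed + 1)
  val <- generate_validation_cohort(vcfg, disc)
  if (perm_validation_labels) {
    set.seed(123)
    val$labels$label <- sample(val$labels$label)
  }
  run_discovery_experiment(disc, validation_bundles = list(ext = val),
                           out_dir = out_dir, n_repetitions = 10,
                           pool_size = 30, seed = seed)
}
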