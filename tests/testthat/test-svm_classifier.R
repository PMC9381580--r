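make_1d_bundle <- function(x_pos = 1, x_neg = -1, n = 2) {
  v <- matrix(c(rep(x_pos, n), rep(x_neg, n)), nrow = 1)
  ids <- paste0("s", seq_len(2 * n))
  cohort_bundle(expression_matrix(v, "pX", "GX", ids),
                sample_annotation(ids, trg_percent = rep(c(100, 20), each = n)))
}

test_that("the symmetric 1-D problem reproduces the analytic max-margin SVM", {
  b <- make_1d_bundle()
  m <- train_svm(b, "pX", cost = 1000)
  # canonical scaling: support vectors sit at decision values +/- 1,
  # the midpoint at 0
  probe <- function(x) {
    em <- expression_matrix(matrix(x, 1), "pX", "GX", paste0("q", seq_along(x)))
    unname(svm_decision_values(m, em))
  }
  expect_equal(probe(0), 0, tolerance = 1e-6)
  expect_equal(probe(c(1, -1)), c(1, -1), tolerance = 1e-6)
  expect_gt(probe(2), 0)
  expect_lt(probe(-2), 0)
})

test_that("training is deterministic and orientation-correct", {
  b <- toy_bundle(seed = 19)
  disc <- extreme_responders(b)
  feats <- disc$expression$probe_ids[1:4]
  m1 <- train_svm(disc, feats)
  m2 <- train_svm(disc, feats)
  expect_identical(m1$weights, m2$weights)
  dv <- svm_decision_values(m1, disc$expression)
  lab <- disc$labels$label
  expect_gt(mean(dv[lab == "positive"]), mean(dv[lab == "negative"]))
  # separable planted signal: full sensitivity at zero FPR on training data
  expect_equal(sensitivity_at_zero_fpr(dv, lab), 1)
})

test_that("decision values honour the frozen-model contract", {
  b <- toy_bundle(seed = 23)
  disc <- extreme_responders(b)
  feats <- disc$expression$probe_ids[1:4]
  m <- train_svm(disc, feats)
  dv1 <- svm_decision_values(m, disc$expression)
  # reapplication is bit-exact
  expect_identical(svm_decision_values(m, disc$expression), dv1)
  # a sample at the frozen feature means scores exactly the bias
  em0 <- expression_matrix(matrix(m$feature_means, ncol = 1),
                           m$feature_list, m$gene_symbols, "at_mean")
  expect_equal(unname(svm_decision_values(m, em0)), m$bias, tolerance = 1e-12)
  # invariance to sample and feature order
  perm <- rev(seq_along(disc$expression$sample_ids))
  em_p <- subset_samples(disc, disc$expression$sample_ids[perm])$expression
  expect_equal(svm_decision_values(m, em_p), dv1[perm])
  set.seed(99)
  fperm <- sample(nrow(disc$expression$values))
  em_f <- expression_matrix(disc$expression$values[fperm, ],
                            disc$expression$probe_ids[fperm],
                            disc$expression$gene_symbols[fperm],
                            disc$expression$sample_ids)
  expect_equal(svm_decision_values(m, em_f), dv1)
  # missing feature is reported
  em_miss <- expression_matrix(disc$expression$values[-1, ],
                               disc$expression$probe_ids[-1],
                               disc$expression$gene_symbols[-1],
                               disc$expression$sample_ids)
  expect_error(svm_decision_values(m, em_miss), "missing")
})

test_that("classify_pcr never calls a training negative pCR", {
  b <- toy_bundle(seed = 29)
  disc <- extreme_responders(b)
  m <- train_svm(disc, disc$expression$probe_ids[1:4])
  calls <- classify_pcr(m, disc$expression)
  expect_true(all(calls[disc$labels$label == "negative"] == "non-pCR"))
  # threshold semantics are strict
  expect_true(all(svm_decision_values(m, disc$expression)[calls == "pCR"] >
                    m$operating_threshold))
})

test_that("model JSON round-trips decision values to 1e-12", {
  b <- toy_bundle(seed = 31)
  disc <- extreme_responders(b)
  ref <- reference_quantiles(quantile_normalize(disc$expression))
  m <- train_svm(disc, disc$expression$probe_ids[1:5], reference = ref)
  path <- withr::local_tempfile(fileext = ".json")
  write_svm_model(m, path)
  m2 <- read_svm_model(path)
  expect_equal(svm_decision_values(m2, disc$expression),
               svm_decision_values(m, disc$expression), tolerance = 1e-12)
  expect_equal(m2$operating_threshold, m$operating_threshold,
               tolerance = 1e-12)
  expect_equal(m2$reference$values, unname(ref$values), tolerance = 1e-12)
})

test_that("cross_validate pools stratified out-of-fold scores", {
  b <- toy_bundle(n_pos = 12, n_neg = 12, effect = 4, seed = 37)
  disc <- extreme_responders(b)
  feats <- disc$expression$probe_ids[1:4]
  r1 <- cross_validate(disc, feats, k = 4, seed = 5)
  expect_equal(r1$auc, 1)
  expect_identical(cross_validate(disc, feats, k = 4, seed = 5), r1)
  expect_error(cross_validate(disc, feats, k = 13, seed = 1), "exceeds")
})

test_that("cross-validation under permuted labels is near chance", {
  b <- toy_bundle(n_pos = 16, n_neg = 16, n_genes = 30, effect = 3, seed = 43)
  disc <- extreme_responders(b)
  feats <- disc$expression$probe_ids[1:4]
  inside <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    perm <- disc
    perm$labels$label <- sample(perm$labels$label)
    a <- cross_validate(perm, feats, k = 4, seed = s)$auc
    inside <- inside + (a >= 0.3 && a <= 0.7)
  }
  expect_gte(inside / 20, 0.8)
})

test_that("LOOCV signature evaluation separates signal from noise lists", {
  b <- toy_bundle(n_pos = 10, n_neg = 10, n_genes = 40, n_inf = 5,
                  effect = 2.5, seed = 47)
  disc <- extreme_responders(b)
  planted <- disc$expression$probe_ids[1:5]
  noise <- disc$expression$probe_ids[31:35]
  expect_gte(as.numeric(evaluate_signature_loocv(disc, planted)), 0.9)
  a0 <- as.numeric(evaluate_signature_loocv(disc, noise))
  expect_true(a0 >= 0 && a0 <= 1)
  # minimal 2 + 2 bundle still returns a value in [0, 1]
  mini <- subset_samples(disc, disc$expression$sample_ids[c(1, 2, 11, 12)])
  a_min <- as.numeric(evaluate_signature_loocv(mini, planted))
  expect_true(a_min >= 0 && a_min <= 1)
})
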