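test_that("resample_split stratifies both classes and is seed-deterministic", {
  lab <- data.frame(sample_id = paste0("s", 1:64),
                    label = rep(c("positive", "negative"), each = 32))
  sp <- resample_split(lab, 0.75, seed = 3)
  expect_length(sp$train_ids, 48)
  expect_length(sp$test_ids, 16)
  in_train <- lab$label[lab$sample_id %in% sp$train_ids]
  expect_equal(sum(in_train == "positive"), 24)
  expect_equal(sum(in_train == "negative"), 24)
  expect_identical(resample_split(lab, 0.75, seed = 3), sp)
  expect_false(identical(resample_split(lab, 0.75, seed = 4)$train_ids,
                         sp$train_ids))
  expect_error(resample_split(data.frame(sample_id = "a", label = "positive"),
                              seed = 1), "both classes")
})

test_that("differential_expression computes the Welch statistic", {
  m <- expression_matrix(rbind(c(0, 1, 2, 3, 4, 5),
                               c(1, 1, 1, 1, 1, 1)),
                         c("pA", "pB"), c("gA", "gB"), paste0("s", 1:6))
  lab <- rep(c("positive", "negative"), each = 3)
  de <- differential_expression(m, lab)
  # equal variances: t = -3 / sqrt(2/3)
  expect_equal(de$t[de$probe_id == "pA"], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_true(de$zero_variance[de$probe_id == "pB"])
  expect_equal(de$p_value[de$probe_id == "pB"], 1)
  # cross-check statistic and p-value against stats::t.test
  set.seed(17)
  m2 <- expression_matrix(matrix(rnorm(10 * 12, 8), 10, 12),
                          paste0("p", 1:10), paste0("g", 1:10),
                          paste0("s", 1:12))
  lab2 <- rep(c("positive", "negative"), each = 6)
  de2 <- differential_expression(m2, lab2)
  for (g in 1:10) {
    ref <- t.test(m2$values[g, 1:6], m2$values[g, 7:12])
    row <- de2[de2$probe_id == paste0("p", g), ]
    expect_equal(row$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_true(!is.unsorted(de2$p_value))
})

test_that("a strongly planted gene ranks first in the pool", {
  first <- 0
  for (s in 1:20) {
    b <- generate_cohort(sim_config(n_genes = 500, n_informative = 1,
                                    effect_size = 3, n_positive = 24,
                                    n_negative = 24, seed = 300 + s))
    de <- differential_expression(b$expression, b$labels$label)
    first <- first + (de$probe_id[1] == attr(b, "informative_genes")[1])
  }
  expect_gte(first / 20, 0.95)
})

test_that("hill climbing finds a separating gene and ignores pure noise", {
  # pool = {separating gene, noise}: brute force over all subsets of size <= 2
  # shows {g1} (and any superset) reaches objective 1, so the forward search
  # must return a set containing g1 with test sensitivity 1
  set.seed(41)
  mk <- function(seed) {
    set.seed(seed)
    v <- rbind(c(rnorm(6, 10), rnorm(6, 4)), rnorm(12, 8))
    em <- expression_matrix(v, c("g_sep", "g_noise"), c("G_SEP", "G_NOISE"),
                            paste0("s", seed * 100 + 1:12))
    cohort_bundle(em, sample_annotation(em$sample_ids,
                                        trg_percent = rep(c(100, 20), each = 6)))
  }
  tr <- mk(1); te <- mk(2)
  res <- hill_climb_select(tr, te, c("g_sep", "g_noise"))
  expect_true("g_sep" %in% res$feature_set)
  expect_equal(res$test_sens, 1)
  # objective path is strictly increasing
  expect_true(all(diff(c(0, attr(res, "objective_path"))) > 0))
  # determinism
  expect_identical(hill_climb_select(tr, te, c("g_sep", "g_noise")), res)
})

test_that("hill climbing returns the empty set when nothing helps", {
  # test positives always score below the best negative on every candidate:
  # make the test-set negatives dominate on both genes
  v_tr <- rbind(c(10, 11, 2, 3), c(5, 6, 1, 2))
  v_te <- rbind(c(2, 3, 10, 11), c(1, 2, 8, 9))
  mk <- function(v, ids) cohort_bundle(
    expression_matrix(v, c("p1", "p2"), c("g1", "g2"), ids),
    sample_annotation(ids, trg_percent = c(100, 100, 20, 20)))
  tr <- mk(v_tr, paste0("tr", 1:4)); te <- mk(v_te, paste0("te", 1:4))
  res <- hill_climb_select(tr, te, c("p1", "p2"))
  expect_length(res$feature_set, 0)
  expect_equal(res$test_sens, 0)
})

test_that("selection_significance is the exact binomial upper tail", {
  expect_equal(selection_significance(10, 10, 0.5), 2^-10, tolerance = 1e-15)
  expect_equal(selection_significance(0, 10, 0.5), 1)
  # independent tail-sum oracle
  oracle <- sum(dbinom(20:500, 500, 0.01))
  expect_equal(selection_significance(20, 500, 0.01), oracle,
               tolerance = 1e-12)
  expect_lt(oracle, 1e-4)
})

test_that("discover_signature is reproducible and warns on degenerate input", {
  b <- toy_bundle(n_pos = 8, n_neg = 8, n_genes = 30, n_inf = 3, effect = 3,
                  seed = 12)
  disc <- extreme_responders(b)
  s1 <- discover_signature(disc, n_repetitions = 5, pool_size = 15, seed = 2)
  s2 <- discover_signature(disc, n_repetitions = 5, pool_size = 15, seed = 2)
  expect_identical(s1$selection_count, s2$selection_count)
  expect_identical(s1$signature, s2$signature)
  # selected sets always come from the per-repetition pools
  for (r in s1$records) expect_true(all(r$selected %in% r$pool))
  expect_true(all(s1$selection_count <= s1$n_repetitions))
  expect_warning(discover_signature(disc, n_repetitions = 1, pool_size = 15,
                                    seed = 2), "degenerate")
  # intermediate labels are rejected
  b_mid <- generate_cohort(sim_config(n_genes = 30, n_positive = 4,
                                      n_negative = 4, n_intermediate = 4,
                                      seed = 1))
  expect_error(discover_signature(b_mid, n_repetitions = 2, seed = 1),
               "positive/negative")
})

test_that("discovery recovers a planted signature at moderate scale", {
  b <- generate_cohort(sim_config(n_genes = 100, n_informative = 5,
                                  effect_size = 2.5, seed = 77))
  sig <- discover_signature(extreme_responders(b), n_repetitions = 40,
                            pool_size = 30, seed = 77)
  planted <- attr(b, "informative_genes")
  hits <- sum(sig$signature$probe_id %in% planted)
  expect_gte(hits, 3)
  p_enrich <- phyper(hits - 1, 5, 95, max(nrow(sig$signature), 1),
                     lower.tail = FALSE)
  expect_lt(p_enrich, 1e-3)
})
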