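# Resampled wrapper feature selection: the cohort of extreme responders is
# repeatedly split into training and test halves; each repetition ranks genes
# by differential expression on the training split and grows a feature set by
# hill climbing, scoring candidate sets by the sensitivity at zero
# false-positive rate of an SVM evaluated on the held-out split. Genes
# selected significantly more often than a binomial null become the
# signature.

#' Stratified train/test resampling split
#'
#' Both classes are represented in both parts (per class,
#' `round(train_fraction * n)` samples train, the rest test).
#'
#' @param labels a `response_labels` data.frame or character vector of labels
#'   (names or `sample_id` column give the sample ids).
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed.
#' @return list with `train_ids` and `test_ids`.
#' @export
resample_split <- function(labels, train_fraction = 0.75, seed = 1) {
  if (is.data.frame(labels)) {
    ids <- labels$sample_id; lab <- labels$label
  } else {
    ids <- names(labels); lab <- as.character(labels)
    if (is.null(ids)) ids <- as.character(seq_along(lab))
  }
  check_two_classes(lab)
  set.seed(seed)
  train <- character(0)
  for (cl in unique(lab)) {
    cl_ids <- ids[lab == cl]
    if (length(cl_ids) < 2L) stop("class '", cl, "' has fewer than 2 members")
    n_tr <- round(train_fraction * length(cl_ids))
    n_tr <- min(max(n_tr, 1L), length(cl_ids) - 1L)
    train <- c(train, sample(cl_ids, n_tr))
  }
  list(train_ids = train, test_ids = setdiff(ids, train))
}

#' Per-gene differential expression (Welch two-sample t)
#'
#' Welch's unequal-variance t statistic on log2 values, positive class minus
#' negative class, with the Welch-Satterthwaite degrees of freedom. Genes
#' with zero variance in both groups are flagged and assigned p = 1.
#'
#' @param mat an [expression_matrix()] of the training samples.
#' @param train_labels labels aligned with the matrix columns
#'   (positive/negative).
#' @param top_k optionally return only the `top_k` most significant genes.
#' @return data.frame (`probe_id`, `gene_symbol`, `t`, `p_value`,
#'   `zero_variance`) sorted by p ascending (ties broken by |t| descending,
#'   then input order).
#' @export
differential_expression <- function(mat, train_labels, top_k = NULL) {
  lab <- as_binary_labels(train_labels)
  pos <- check_two_classes(lab)
  X1 <- mat$values[, pos, drop = FALSE]
  X2 <- mat$values[, !pos, drop = FALSE]
  n1 <- ncol(X1); n2 <- ncol(X2)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  zero <- se2 == 0
  tt <- ifelse(zero, 0, (m1 - m2) / sqrt(se2))
  df <- ifelse(zero, 1,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))))
  p <- ifelse(zero, 1, 2 * pt(-abs(tt), df = df))
  ord <- order(p, -abs(tt), seq_along(p))
  out <- data.frame(probe_id = mat$probe_ids, gene_symbol = mat$gene_symbols,
                    t = tt, p_value = p, zero_variance = zero,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ]
  out
}

#' Greedy hill-climbing feature selection under the zero-FPR objective
#'
#' Forward search over a candidate pool: starting from the empty set, each
#' step adds the candidate whose linear SVM (trained on the training bundle)
#' most increases the sensitivity at zero false-positive rate on the test
#' bundle; the search stops when no addition strictly improves the objective
#' (or it reaches 1, the maximum). With `allow_swap = TRUE`, removals and
#' one-for-one swaps are also evaluated at each step. Ties are broken towards
#' the smaller feature set, then towards the better differential-expression
#' rank (pool order).
#'
#' @param train_bundle,test_bundle [cohort_bundle()]s with positive/negative
#'   labels, same gene universe.
#' @param candidate_pool character vector of probe ids, in differential-
#'   expression rank order.
#' @param cost SVM cost parameter.
#' @param allow_swap evaluate removals and swaps in addition to additions.
#' @param max_features optional cap on the feature-set size.
#' @return list with `feature_set` (probe ids, in order of addition) and
#'   `test_sens` (the achieved objective); the accepted-move objective
#'   sequence is attached as attribute `objective_path`.
#' @export
hill_climb_select <- function(train_bundle, test_bundle, candidate_pool,
                              cost = 1, allow_swap = FALSE,
                              max_features = Inf) {
  if (!length(candidate_pool)) stop("candidate_pool is empty")
  ytr <- train_bundle$labels$label
  yte <- test_bundle$labels$label
  check_two_classes(ytr); check_two_classes(yte)
  pool_idx_tr <- match(candidate_pool, train_bundle$expression$probe_ids)
  pool_idx_te <- match(candidate_pool, test_bundle$expression$probe_ids)
  if (anyNA(pool_idx_tr) || anyNA(pool_idx_te))
    stop("candidate_pool contains probes absent from the bundles")
  Xtr <- t(train_bundle$expression$values[pool_idx_tr, , drop = FALSE])
  Xte <- t(test_bundle$expression$values[pool_idx_te, , drop = FALSE])
  eval_set <- function(cols) {
    fit <- fit_linear_svm(Xtr[, cols, drop = FALSE], ytr, cost)
    sensitivity_at_zero_fpr(decision_from_fit(fit, Xte[, cols, drop = FALSE]), yte)
  }
  current <- integer(0)
  best <- 0
  path <- numeric(0)
  eps <- 1e-12
  repeat {
    if (best >= 1 - eps) break
    move <- NULL; move_obj <- best
    if (length(current) < max_features) {
      for (g in setdiff(seq_along(candidate_pool), current)) {
        obj <- eval_set(c(current, g))
        if (obj > move_obj + eps) { move_obj <- obj; move <- c(current, g) }
      }
    }
    if (allow_swap && length(current)) {
      for (d in current) {
        rest <- setdiff(current, d)
        if (length(rest)) {
          obj <- eval_set(rest)
          if (obj > move_obj + eps) { move_obj <- obj; move <- rest }
        }
        for (g in setdiff(seq_along(candidate_pool), current)) {
          obj <- eval_set(c(rest, g))
          if (obj > move_obj + eps) { move_obj <- obj; move <- c(rest, g) }
        }
      }
    }
    if (is.null(move)) break
    current <- move; best <- move_obj
    path <- c(path, best)
  }
  structure(list(feature_set = candidate_pool[current], test_sens = best),
            objective_path = path)
}

#' Selection-frequency significance under a binomial null
#'
#' Under the null that each repetition picks its selected set uniformly at
#' random from its candidate pool, a given gene is selected with probability
#' `null_rate` (the mean selected-set size divided by the pool size) in each
#' of `n_repetitions` independent repetitions. The p-value is the exact
#' upper binomial tail P\[X >= count\].
#'
#' @param selection_count integer vector of per-gene selection counts.
#' @param n_repetitions number of repetitions.
#' @param null_rate per-repetition null selection probability, in (0, 1).
#' @return numeric vector of p-values.
#' @export
selection_significance <- function(selection_count, n_repetitions, null_rate) {
  stopifnot(null_rate > 0, null_rate < 1,
            all(selection_count >= 0), all(selection_count <= n_repetitions))
  pbinom(selection_count - 1, n_repetitions, null_rate, lower.tail = FALSE)
}

#' Discover a stable transcript signature by resampled hill climbing
#'
#' Orchestrates the full wrapper-selection procedure on a cohort of extreme
#' responders: `n_repetitions` stratified 3/4 - 1/4 splits; per repetition a
#' Welch differential-expression ranking on the training split, a candidate
#' pool of the `pool_size` top genes, and hill climbing towards maximal test
#' sensitivity at zero false-positive rate; finally an exact binomial test on
#' each gene's selection frequency. Genes with p < `alpha` form the
#' signature. The whole procedure is a pure function of (bundle, parameters,
#' seed): the master seed spawns one sub-seed per repetition, so results do
#' not depend on execution order.
#'
#' @param bundle a [cohort_bundle()] restricted to positive/negative labels.
#' @param n_repetitions number of resampling repetitions (the study design
#'   uses 500).
#' @param alpha selection-frequency significance cutoff.
#' @param pool_size candidate-pool size (top differentially expressed genes
#'   per repetition).
#' @param train_fraction fraction of each class used for training per split.
#' @param cost SVM cost.
#' @param allow_swap passed to [hill_climb_select()].
#' @param seed master seed.
#' @param verbose log progress every 10 repetitions.
#' @return A list with class `signature_result`: `selection_count` (named per
#'   probe), `n_repetitions`, `null_rate`, `p_value`, `signature` (data.frame
#'   `probe_id`/`gene_symbol`, sorted by count descending) and `records`
#'   (per-repetition seed, pool, selected set, test sensitivity).
#' @export
discover_signature <- function(bundle, n_repetitions = 500, alpha = 0.05,
                               pool_size = 100, train_fraction = 0.75,
                               cost = 1, allow_swap = FALSE, seed = 1,
                               verbose = FALSE) {
  lab <- bundle$labels$label
  if (!all(lab %in% c("positive", "negative")))
    stop("discovery bundle must contain only positive/negative labels; see extreme_responders()")
  if (n_repetitions < 2)
    warning("signature discovery with n_repetitions < 2 is degenerate; ",
            "selection frequencies carry no stability information")
  probes <- bundle$expression$probe_ids
  counts <- setNames(integer(length(probes)), probes)
  rep_seeds <- spawn_seeds(seed, n_repetitions)
  records <- vector("list", n_repetitions)
  for (i in seq_len(n_repetitions)) {
    sp <- resample_split(bundle$labels, train_fraction, seed = rep_seeds[i])
    tr <- subset_samples(bundle, sp$train_ids)
    te <- subset_samples(bundle, sp$test_ids)
    de <- differential_expression(tr$expression, tr$labels$label,
                                  top_k = pool_size)
    hc <- hill_climb_select(tr, te, de$probe_id, cost = cost,
                            allow_swap = allow_swap)
    counts[hc$feature_set] <- counts[hc$feature_set] + 1L
    records[[i]] <- list(seed = rep_seeds[i], pool = de$probe_id,
                         selected = hc$feature_set, test_sens = hc$test_sens)
    if (verbose && i %% 10 == 0)
      message(sprintf("repetition %d/%d (last test sensitivity %.2f)",
                      i, n_repetitions, hc$test_sens))
  }
  mean_size <- mean(vapply(records, function(r) length(r$selected), numeric(1)))
  null_rate <- min(max(mean_size / pool_size, 1e-12), 1 - 1e-12)
  p <- selection_significance(counts, n_repetitions, null_rate)
  sig_idx <- which(p < alpha & counts > 0)
  sig_idx <- sig_idx[order(-counts[sig_idx])]
  structure(list(selection_count = counts, n_repetitions = n_repetitions,
                 null_rate = null_rate, p_value = p,
                 signature = data.frame(
                   probe_id = probes[sig_idx],
                   gene_symbol = bundle$expression$gene_symbols[sig_idx],
                   selection_count = unname(counts[sig_idx]),
                   p_value = unname(p[sig_idx]),
                   stringsAsFactors = FALSE),
                 records = records,
                 config = list(alpha = alpha, pool_size = pool_size,
                               train_fraction = train_fraction, cost = cost,
                               allow_swap = allow_swap, seed = seed)),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result: %d transcripts at p < %g over %d repetitions (null rate %.4f)\n",
              nrow(x$signature), x$config$alpha, x$n_repetitions, x$null_rate))
  if (nrow(x$signature)) print(head(x$signature, 25))
  invisible(x)
}

#' Write a discovered signature to JSON
#'
#' @param sig a `signature_result` (or data.frame with `gene_symbol` and
#'   optionally `probe_id`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_json <- function(sig, path) {
  df <- if (inherits(sig, "signature_result")) sig$signature else sig
  jsonlite::write_json(
    list(schema = "pcrsig_signature/1",
         genes = df[, intersect(c("gene_symbol", "probe_id", "selection_count",
                                  "p_value"), names(df)), drop = FALSE]),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
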