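# The normalization-free second classifier: a per-sample score defined as
# the sum of expression of one gene multiset divided by the sum of another.
# Being a ratio of sums of raw intensities, it is invariant to any global
# positive rescaling of the array, so it can be applied to data "as is".

#' Construct a ratio score definition
#'
#' @param numerator_genes character vector of gene symbols summed in the
#'   numerator (may share genes with the denominator).
#' @param denominator_genes character vector of gene symbols summed in the
#'   denominator; must be non-empty.
#' @return A list with class `ratio_score`.
#' @export
ratio_score <- function(numerator_genes, denominator_genes) {
  if (!length(denominator_genes)) stop("denominator gene set must be non-empty")
  structure(list(numerator_genes = as.character(numerator_genes),
                 denominator_genes = as.character(denominator_genes)),
            class = "ratio_score")
}

#' @export
print.ratio_score <- function(x, ...) {
  cat(sprintf("ratio_score: %d numerator / %d denominator genes (%d shared)\n",
              length(x$numerator_genes), length(x$denominator_genes),
              length(intersect(x$numerator_genes, x$denominator_genes))))
  invisible(x)
}

#' The published 21-gene ratio score
#'
#' The printed formula of the second classifier: 14 numerator and 12
#' denominator symbols (7 genes appear in both sums), given in the legacy
#' nomenclature of the formula; [gene_alias_map()] resolves the legacy names
#' to current symbols. MCM5 and STARD3 belong to the 21-transcript signature
#' but to neither sum.
#'
#' @return A [ratio_score()].
#' @export
published_score <- function() {
  ratio_score(
    numerator_genes = c("KIAA1598", "ASPM", "TMPO", "HOMER1", "CXCL10",
                        "CENPL", "BRCA1", "FZD10", "C19orf51", "C20orf26",
                        "CASC5", "CCNB1", "FANCM", "BLM"),
    denominator_genes = c("CGREF1", "TNPO3", "XPO1", "TSNAX", "CENPL",
                          "FANCM", "FZD10", "C19orf51", "C20orf26", "CCNB1",
                          "CSPP1", "BLM"))
}

# Collapse an expression matrix to one linear-scale row per canonical symbol
# of `genes`; returns genes x samples matrix of positive values.
linear_gene_matrix <- function(mat, genes, values_are_log2,
                               missing = c("fail", "drop")) {
  missing <- match.arg(missing)
  sub <- subset_to_signature(mat, genes, missing = missing)
  E <- sub$values
  if (values_are_log2) E <- 2^E
  if (nrow(E) && any(E <= 0)) {
    bad <- which(E <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("nonpositive expression for gene '%s' in sample '%s'; ratio scores need positive intensities",
                 sub$gene_symbols[bad[1L]], sub$sample_ids[bad[2L]]))
  }
  rownames(E) <- sub$gene_symbols
  E
}

#' Compute per-sample ratio scores
#'
#' For each sample, the sum of (linear-scale) expression over the numerator
#' multiset divided by the sum over the denominator multiset; a gene listed
#' in both sets contributes to both sums. No normalization is applied.
#'
#' @param mat an [expression_matrix()].
#' @param score a [ratio_score()].
#' @param values_are_log2 if `TRUE` (default) matrix values are log2
#'   intensities and are exponentiated back to the linear scale first; set to
#'   `FALSE` for raw positive intensities.
#' @param missing `"fail"` to error on absent genes, `"drop"` to warn and
#'   leave them out of the sums (the missing-genes application scenario).
#' @return Named numeric vector of per-sample scores.
#' @export
compute_ratio_score <- function(mat, score, values_are_log2 = TRUE,
                                missing = c("fail", "drop")) {
  missing <- match.arg(missing)
  genes <- unique(c(score$numerator_genes, score$denominator_genes))
  E <- linear_gene_matrix(mat, genes, values_are_log2, missing)
  num <- canonical_symbol(score$numerator_genes)
  den <- canonical_symbol(score$denominator_genes)
  num <- num[num %in% rownames(E)]
  den <- den[den %in% rownames(E)]
  if (!length(den)) stop("no denominator gene present in the matrix")
  s <- colSums(E[num, , drop = FALSE]) / colSums(E[den, , drop = FALSE])
  setNames(s, mat$sample_ids)
}

# Objective and score evaluation on a precomputed gene x sample matrix,
# using logical membership vectors over the gene universe.
score_from_state <- function(E, num, den) {
  n <- if (any(num)) colSums(E[num, , drop = FALSE]) else rep(0, ncol(E))
  n / colSums(E[den, , drop = FALSE])
}

#' Train a ratio score by greedy local search from one random start
#'
#' Starts from a seeded random assignment of the gene universe to the
#' numerator and/or denominator. At each step every single modification of
#' the score — adding or removing one gene to or from the numerator or the
#' denominator (a move emptying the denominator is inadmissible) — is
#' evaluated, and the move that maximally increases the training sensitivity
#' at zero false-positive rate is accepted; the search stops at a local
#' maximum. Deterministic under `seed` (ties resolved in a fixed gene-by-side
#' enumeration order).
#'
#' @param train_bundle,test_bundle [cohort_bundle()]s with positive/negative
#'   labels.
#' @param gene_universe character vector of candidate gene symbols (the
#'   21-gene signature in the published design).
#' @param seed integer seed for the initial assignment.
#' @param values_are_log2 passed to the score computation.
#' @return list with `score` (a [ratio_score()]), `train_sens`, `test_sens`;
#'   the accepted-move objective sequence is attached as attribute
#'   `objective_path`.
#' @export
local_search_score <- function(train_bundle, test_bundle, gene_universe,
                               seed = 1, values_are_log2 = TRUE) {
  ytr <- train_bundle$labels$label
  yte <- test_bundle$labels$label
  check_two_classes(ytr); check_two_classes(yte)
  Etr <- linear_gene_matrix(train_bundle$expression, gene_universe, values_are_log2)
  Ete <- linear_gene_matrix(test_bundle$expression, gene_universe, values_are_log2)
  G <- nrow(Etr)
  syms <- rownames(Etr)
  set.seed(seed)
  num <- runif(G) < 0.5
  den <- runif(G) < 0.5
  if (!any(den)) den[sample.int(G, 1L)] <- TRUE
  objective <- function(num, den)
    sensitivity_at_zero_fpr(score_from_state(Etr, num, den), ytr)
  best <- objective(num, den)
  path <- numeric(0)
  eps <- 1e-12
  repeat {
    move <- NULL; move_obj <- best
    for (g in seq_len(G)) {
      n2 <- num; n2[g] <- !n2[g]
      obj <- objective(n2, den)
      if (obj > move_obj + eps) { move_obj <- obj; move <- list(n2, den) }
      d2 <- den; d2[g] <- !d2[g]
      if (any(d2)) {
        obj <- objective(num, d2)
        if (obj > move_obj + eps) { move_obj <- obj; move <- list(num, d2) }
      }
    }
    if (is.null(move)) break
    num <- move[[1L]]; den <- move[[2L]]; best <- move_obj
    path <- c(path, best)
  }
  sc <- ratio_score(syms[num], syms[den])
  test_sens <- sensitivity_at_zero_fpr(score_from_state(Ete, num, den), yte)
  structure(list(score = sc, train_sens = best, test_sens = test_sens),
            objective_path = path)
}

#' Train the score classifier by random-restart local search
#'
#' The published training protocol: the extreme-response cohort is split once
#' into stratified training and test halves; `n_restarts` independent local
#' searches are run on the training half from random initial assignments, and
#' every trained score is evaluated on the test half. The score with maximal
#' test sensitivity is selected (ties: higher training sensitivity, then
#' fewer genes in total, then the earlier restart). With `folds = 2` both
#' halves additionally swap roles and the best score across both directions
#' is returned.
#'
#' @param bundle a [cohort_bundle()] restricted to positive/negative labels.
#' @param gene_universe candidate gene symbols; defaults to the 21-gene
#'   signature.
#' @param n_restarts number of random restarts (100 in the published design).
#' @param seed master seed; spawns the split and the restart seeds.
#' @param folds 1 for a single split, 2 to also swap the halves.
#' @param values_are_log2 passed through.
#' @return A [ratio_score()] with attributes `train_sens`, `test_sens` and
#'   `restart_index`.
#' @export
train_score_classifier <- function(bundle, gene_universe = signature_21()$gene_symbol,
                                   n_restarts = 100, seed = 1, folds = 1,
                                   values_are_log2 = TRUE) {
  lab <- bundle$labels$label
  if (!all(lab %in% c("positive", "negative")))
    stop("training bundle must contain only positive/negative labels")
  stopifnot(folds %in% c(1, 2))
  seeds <- spawn_seeds(seed, n_restarts + 1L)
  sp <- resample_split(bundle$labels, train_fraction = 0.5, seed = seeds[1L])
  halves <- list(list(train = sp$train_ids, test = sp$test_ids))
  if (folds == 2)
    halves[[2L]] <- list(train = sp$test_ids, test = sp$train_ids)
  best <- NULL
  for (h in seq_along(halves)) {
    tr <- subset_samples(bundle, halves[[h]]$train)
    te <- subset_samples(bundle, halves[[h]]$test)
    for (r in seq_len(n_restarts)) {
      res <- local_search_score(tr, te, gene_universe, seed = seeds[r + 1L],
                                values_are_log2 = values_are_log2)
      size <- length(res$score$numerator_genes) + length(res$score$denominator_genes)
      cand <- list(score = res$score, train_sens = res$train_sens,
                   test_sens = res$test_sens, size = size,
                   restart = r + (h - 1L) * n_restarts)
      if (is.null(best) ||
          cand$test_sens > best$test_sens + 1e-12 ||
          (abs(cand$test_sens - best$test_sens) <= 1e-12 &&
           (cand$train_sens > best$train_sens + 1e-12 ||
            (abs(cand$train_sens - best$train_sens) <= 1e-12 &&
             cand$size < best$size))))
        best <- cand
    }
  }
  out <- best$score
  attr(out, "train_sens") <- best$train_sens
  attr(out, "test_sens") <- best$test_sens
  attr(out, "restart_index") <- best$restart
  out
}

#' Operating threshold for a ratio score
#'
#' Mirrors the SVM's zero-false-positive rule: the threshold sits just above
#' the largest training-negative score, so no training negative is called
#' pCR.
#'
#' @param scores training scores.
#' @param labels training labels.
#' @return Numeric threshold; classify pCR when score > threshold.
#' @export
score_threshold <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  check_two_classes(labels)
  max_neg <- max(scores[labels == "negative"])
  max_neg + max(1e-12, abs(max_neg) * 1e-12)
}

#' Write / read a ratio score definition as JSON
#'
#' @param score a [ratio_score()].
#' @param path file path.
#' @return `path` (write) or a [ratio_score()] (read).
#' @export
write_ratio_score <- function(score, path) {
  jsonlite::write_json(list(schema = "pcrsig_ratio_score/1",
                            numerator = score$numerator_genes,
                            denominator = score$denominator_genes),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ratio_score
#' @export
read_ratio_score <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ratio_score(obj$numerator, obj$denominator)
}
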