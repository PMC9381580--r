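# Linear SVM training, freezing and application. The final classifier is a
# frozen object: feature list, standardization parameters, weight vector,
# reference quantile distribution and an operating threshold chosen so that
# no training negative is ever called pCR.

# Low-level linear SVM on a samples x features matrix. Standardizes features
# to zero mean / unit sd on the training data, fits a soft-margin linear SVM
# and returns the decision function in raw-feature coordinates component
# form (standardize, then w . x + b). Decision values are positive towards
# the "positive" class regardless of label ordering.
fit_linear_svm <- function(X, y, cost = 1) {
  means <- colMeans(X)
  sds <- apply(X, 2L, sd)
  sds[sds == 0] <- 1          # constant feature carries no information
  Xs <- sweep(sweep(X, 2L, means, "-"), 2L, sds, "/")
  yf <- factor(y, levels = c("positive", "negative"))
  m <- e1071::svm(Xs, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  if (m$levels[m$labels[1L]] != "positive") { w <- -w; b <- -b }
  list(weights = w, bias = b, feature_means = means, feature_sds = sds)
}

decision_from_fit <- function(fit, X) {
  Xs <- sweep(sweep(X, 2L, fit$feature_means, "-"), 2L, fit$feature_sds, "/")
  drop(Xs %*% fit$weights) + fit$bias
}

# Resolve a signature argument (signature_result, data.frame from
# signature_21(), or character vector of probe ids / gene symbols) to the
# row indices of an expression matrix.
resolve_features <- function(mat, signature) {
  if (inherits(signature, "signature_result")) signature <- signature$signature
  if (is.data.frame(signature)) {
    ids <- if ("probe_id" %in% names(signature) &&
               all(signature$probe_id %in% mat$probe_ids)) signature$probe_id
           else signature$gene_symbol
  } else ids <- as.character(signature)
  idx <- match(ids, mat$probe_ids)
  if (anyNA(idx)) {
    canon <- canonical_symbol(mat$gene_symbols)
    idx2 <- match(canonical_symbol(ids), canon)
    idx[is.na(idx)] <- idx2[is.na(idx)]
  }
  if (anyNA(idx))
    stop("signature features not found in matrix: ",
         paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Train the final linear SVM classifier
#'
#' Fits a soft-margin linear SVM on the signature features of a cohort of
#' extreme responders (positive/negative labels only), with features
#' standardized to zero mean and unit standard deviation on the training
#' data. The operating threshold is set just above the largest
#' training-negative decision value, so classifying at the threshold can
#' never call a training negative pCR.
#'
#' @param bundle a [cohort_bundle()] restricted to positive/negative labels.
#' @param signature features to use: a `signature_result`, a data.frame with
#'   `probe_id`/`gene_symbol` columns, or a character vector.
#' @param cost soft-margin cost parameter C.
#' @param reference optional [reference_quantiles()] frozen with the model so
#'   external cohorts can be aligned before application.
#' @param seed recorded in the provenance (the fit itself is deterministic).
#' @return A list with class `trained_svm`: `feature_list`, `gene_symbols`,
#'   `weights`, `bias`, `feature_means`, `feature_sds`, `reference`,
#'   `operating_threshold`, `training_provenance`.
#' @export
train_svm <- function(bundle, signature, cost = 1, reference = NULL,
                      seed = NA_integer_) {
  lab <- bundle$labels$label
  if (!all(lab %in% c("positive", "negative")))
    stop("training bundle must contain only positive/negative labels")
  check_two_classes(lab)
  idx <- resolve_features(bundle$expression, signature)
  X <- t(bundle$expression$values[idx, , drop = FALSE])
  fit <- fit_linear_svm(X, lab, cost)
  dv <- decision_from_fit(fit, X)
  max_neg <- max(dv[lab == "negative"])
  thr <- max_neg + max(1e-12, abs(max_neg) * 1e-12)
  structure(list(feature_list = bundle$expression$probe_ids[idx],
                 gene_symbols = bundle$expression$gene_symbols[idx],
                 weights = fit$weights, bias = fit$bias,
                 feature_means = fit$feature_means,
                 feature_sds = fit$feature_sds,
                 reference = reference,
                 operating_threshold = thr,
                 training_provenance = list(n_pos = sum(lab == "positive"),
                                            n_neg = sum(lab == "negative"),
                                            cost = cost, seed = seed)),
            class = "trained_svm")
}

#' @export
print.trained_svm <- function(x, ...) {
  cat(sprintf("trained_svm: %d features, threshold %.4g (trained on %d pos / %d neg)\n",
              length(x$feature_list), x$operating_threshold,
              x$training_provenance$n_pos, x$training_provenance$n_neg))
  invisible(x)
}

#' Decision values of a frozen SVM
#'
#' Standardization uses the frozen training means and standard deviations;
#' no quantity is re-estimated from the new data.
#'
#' @param model a `trained_svm`.
#' @param mat an [expression_matrix()] containing all model features (matched
#'   by probe id, falling back to aliased gene symbol).
#' @return Named numeric vector of per-sample decision values.
#' @export
svm_decision_values <- function(model, mat) {
  idx <- match(model$feature_list, mat$probe_ids)
  if (anyNA(idx)) {
    canon <- canonical_symbol(mat$gene_symbols)
    idx2 <- match(canonical_symbol(model$gene_symbols), canon)
    idx[is.na(idx)] <- idx2[is.na(idx)]
  }
  if (anyNA(idx))
    stop("matrix is missing model features: ",
         paste(model$gene_symbols[is.na(idx)], collapse = ", "))
  X <- t(mat$values[idx, , drop = FALSE])
  dv <- decision_from_fit(model, X)
  names(dv) <- mat$sample_ids
  dv
}

#' Classify samples as pCR / non-pCR
#'
#' A sample is called pCR when its decision value exceeds the model's
#' operating threshold (strictly), the zero-false-positive operating rule.
#'
#' @inheritParams svm_decision_values
#' @return Named character vector of `"pCR"` / `"non-pCR"` calls.
#' @export
classify_pcr <- function(model, mat) {
  dv <- svm_decision_values(model, mat)
  setNames(ifelse(dv > model$operating_threshold, "pCR", "non-pCR"), names(dv))
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("k exceeds the size of class '", cl, "'")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Stratified k-fold cross-validation of the SVM on a signature
#'
#' Out-of-fold decision values are pooled into a single score vector and
#' evaluated once (micro-averaged), producing one ROC rather than per-fold
#' averages.
#'
#' @inheritParams train_svm
#' @param k number of folds (<= smallest class size).
#' @param seed integer seed for the fold assignment.
#' @return An [eval_report()]; the pooled out-of-fold scores are attached as
#'   attribute `scores`.
#' @export
cross_validate <- function(bundle, signature, k = 4, cost = 1, seed = 1) {
  lab <- bundle$labels$label
  check_two_classes(lab)
  idx <- resolve_features(bundle$expression, signature)
  X <- t(bundle$expression$values[idx, , drop = FALSE])
  set.seed(seed)
  fold <- stratified_folds(lab, k)
  dv <- numeric(length(lab))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fit_linear_svm(X[tr, , drop = FALSE], lab[tr], cost)
    dv[!tr] <- decision_from_fit(fit, X[!tr, , drop = FALSE])
  }
  rep <- eval_report(dv, lab)
  attr(rep, "scores") <- setNames(dv, bundle$expression$sample_ids)
  rep
}

#' Evaluate an arbitrary gene signature by leave-one-out cross-validation
#'
#' The generic re-evaluation engine for published signatures: a linear-kernel
#' SVM is trained n times on n - 1 samples, the held-out decision values are
#' pooled and a single AUC is computed.
#'
#' @param bundle a [cohort_bundle()] with positive/negative labels.
#' @param gene_list character vector of gene symbols (aliases resolved) or
#'   probe ids.
#' @param cost soft-margin cost.
#' @return AUC of the pooled held-out decision values; the full
#'   [eval_report()] is attached as attribute `report`.
#' @export
evaluate_signature_loocv <- function(bundle, gene_list, cost = 1) {
  lab <- bundle$labels$label
  if (sum(lab == "positive") < 2 || sum(lab == "negative") < 2)
    stop("need at least two samples per class")
  idx <- resolve_features(bundle$expression, gene_list)
  if (!length(idx)) stop("no signature gene found in the matrix")
  X <- t(bundle$expression$values[idx, , drop = FALSE])
  n <- nrow(X)
  dv <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_linear_svm(X[-i, , drop = FALSE], lab[-i], cost)
    dv[i] <- decision_from_fit(fit, X[i, , drop = FALSE])
  }
  out <- auc(dv, lab)
  attr(out, "report") <- eval_report(dv, lab)
  out
}

# ---------------------------------------------------------------------------
# Model serialization
# ---------------------------------------------------------------------------

#' Write a trained SVM model to JSON
#'
#' The artifact bundles everything needed for frozen application: features,
#' weights, standardization parameters, operating threshold, the reference
#' quantile distribution and the symbol alias map, with a schema version.
#'
#' @param model a `trained_svm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svm_model <- function(model, path) {
  obj <- list(schema = "pcrsig_svm_model/1",
              feature_list = model$feature_list,
              gene_symbols = model$gene_symbols,
              weights = unname(model$weights),
              bias = model$bias,
              feature_means = unname(model$feature_means),
              feature_sds = unname(model$feature_sds),
              operating_threshold = model$operating_threshold,
              reference = if (!is.null(model$reference))
                list(values = unname(model$reference$values),
                     n_source_samples = model$reference$n_source_samples),
              alias_map = as.list(gene_alias_map()),
              training_provenance = model$training_provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trained SVM model from JSON
#'
#' @param path path to a file written by [write_svm_model()].
#' @return A `trained_svm`.
#' @export
read_svm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "pcrsig_svm_model/1"))
    stop("unrecognized model schema: ", obj$schema)
  ref <- if (!is.null(obj$reference) && length(obj$reference))
    structure(list(values = as.numeric(obj$reference$values),
                   n_source_samples = obj$reference$n_source_samples),
              class = "reference_quantiles")
  structure(list(feature_list = obj$feature_list,
                 gene_symbols = obj$gene_symbols,
                 weights = setNames(as.numeric(obj$weights), obj$feature_list),
                 bias = obj$bias,
                 feature_means = setNames(as.numeric(obj$feature_means), obj$feature_list),
                 feature_sds = setNames(as.numeric(obj$feature_sds), obj$feature_list),
                 reference = ref,
                 operating_threshold = obj$operating_threshold,
                 training_provenance = obj$training_provenance),
            class = "trained_svm")
}
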