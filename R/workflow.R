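# End-to-end orchestration of the two experiments: (1) discovery ->
# cross-validation -> final SVM -> frozen application to external cohorts;
# (2) score computation -> correlation with regression grade -> median-split
# survival stratification. Artifacts are deterministic JSON/TSV (no
# timestamps), so a rerun with the same seed is byte-identical.

write_json_artifact <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

report_to_list <- function(report) {
  list(auc = report$auc, sens_at_zero_fpr = report$sens_at_zero_fpr,
       n_positive = report$n_positive, n_negative = report$n_negative,
       roc_points = report$roc_points, pr_points = report$pr_points)
}

#' Run the discovery experiment end to end
#'
#' Pipeline: restrict the discovery cohort to extreme responders, quantile-
#' normalize, discover the signature by resampled hill climbing,
#' cross-validate it, train the final SVM, freeze the reference quantile
#' distribution, and apply the frozen model (alignment + decision values, no
#' retraining) to a full-range cohort and to any external validation
#' cohorts. Training never reads validation data or labels, so the training
#' artifacts (`signature.json`, `model.json`) are unchanged by any
#' modification of the validation cohorts.
#'
#' @param discovery_bundle extreme-response [cohort_bundle()] (intermediates,
#'   if present, are dropped for training).
#' @param full_bundle optional full-range cohort the frozen model is applied
#'   to, and whose normalized expression provides the reference distribution;
#'   defaults to the discovery cohort.
#' @param validation_bundles named list of external [cohort_bundle()]s,
#'   aligned to the frozen reference before application.
#' @param out_dir directory for JSON artifacts; `NULL` to skip writing.
#' @param n_repetitions,pool_size,alpha,train_fraction,cost,allow_swap
#'   discovery parameters; see [discover_signature()].
#' @param k_folds folds for [cross_validate()].
#' @param seed master seed.
#' @param positive_definition how validation reports define the positive
#'   class: `"pcr"` (positives vs all others, the full-range evaluation) —
#'   only samples with known labels are evaluated.
#' @return list with `signature`, `model`, `cv_report`, `full_report`,
#'   `validation_reports`, and `paths` of written artifacts.
#' @export
run_discovery_experiment <- function(discovery_bundle, full_bundle = NULL,
                                     validation_bundles = list(),
                                     out_dir = NULL, n_repetitions = 100,
                                     pool_size = 100, alpha = 0.05,
                                     train_fraction = 0.75, cost = 1,
                                     allow_swap = FALSE, k_folds = 4,
                                     seed = 1, positive_definition = "pcr") {
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  disc <- step("derive_labels", extreme_responders(discovery_bundle))
  disc$expression <- step("quantile_normalize", quantile_normalize(disc$expression))
  if (is.null(full_bundle)) full_bundle <- discovery_bundle
  full_norm <- step("quantile_normalize", quantile_normalize(full_bundle$expression))
  sig <- step("discover_signature",
              discover_signature(disc, n_repetitions = n_repetitions,
                                 alpha = alpha, pool_size = pool_size,
                                 train_fraction = train_fraction, cost = cost,
                                 allow_swap = allow_swap, seed = seed))
  if (!nrow(sig$signature))
    stop("stage 'discover_signature' failed: empty signature at alpha = ", alpha)
  cv <- step("cross_validate",
             cross_validate(disc, sig, k = k_folds, cost = cost, seed = seed))
  ref <- step("reference_quantiles", reference_quantiles(full_norm))
  model <- step("train_svm", train_svm(disc, sig, cost = cost, reference = ref,
                                       seed = seed))
  # frozen application to the full-range cohort
  full_report <- step("apply_full", {
    dv <- svm_decision_values(model, full_norm)
    lab <- full_bundle$labels$label
    keep <- lab != "unknown"
    eval_report(dv[keep], ifelse(lab[keep] == "positive", "positive", "negative"))
  })
  validation_reports <- lapply(validation_bundles, function(vb) {
    step("apply_validation", {
      aligned <- align_to_reference(vb$expression, model$reference)
      dv <- svm_decision_values(model, aligned)
      lab <- vb$labels$label
      keep <- lab != "unknown"
      labels2 <- ifelse(lab[keep] == "positive", "positive", "negative")
      rep <- eval_report(dv[keep], labels2)
      calls <- ifelse(dv > model$operating_threshold, "pCR", "non-pCR")
      fp <- sum(calls[keep] == "pCR" & labels2 == "negative")
      list(report = rep, decision_values = dv, calls = calls,
           false_positives_at_threshold = fp)
    })
  })
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(signature = file.path(out_dir, "signature.json"),
               model = file.path(out_dir, "model.json"),
               cv = file.path(out_dir, "cv_report.json"))
    write_signature_json(sig, paths["signature"])
    write_svm_model(model, paths["model"])
    write_json_artifact(report_to_list(cv), paths["cv"])
    write_json_artifact(report_to_list(full_report),
                        full <- file.path(out_dir, "full_cohort_report.json"))
    paths <- c(paths, full_cohort = full)
    for (nm in names(validation_reports)) {
      p <- file.path(out_dir, paste0("validation_", nm, ".json"))
      vr <- validation_reports[[nm]]
      write_json_artifact(c(report_to_list(vr$report),
                            list(false_positives_at_threshold =
                                   vr$false_positives_at_threshold)), p)
      paths <- c(paths, setNames(p, paste0("validation_", nm)))
    }
  }
  list(signature = sig, model = model, cv_report = cv,
       full_report = full_report, validation_reports = validation_reports,
       paths = paths)
}

#' Run the prognosis experiment
#'
#' Computes per-sample classification scores (SVM decision values for a
#' `trained_svm`, ratio scores for a `ratio_score`, or a supplied numeric
#' vector), correlates them with the tumour regression grade where TRG is
#' recorded, splits the cohort at the median score, and compares survival
#' between the halves by Kaplan-Meier estimates and the log-rank test for
#' each available endpoint (overall and disease-free survival).
#'
#' @param bundle a [cohort_bundle()] with survival annotation.
#' @param classifier a `trained_svm`, a [ratio_score()], or a numeric vector
#'   of scores named by sample id.
#' @param out_dir optional directory for `scores.tsv` and `km.json`.
#' @param values_are_log2 used when `classifier` is a ratio score.
#' @param align if `TRUE` and the classifier is a `trained_svm` with a frozen
#'   reference, the expression is aligned to it first.
#' @return list with `scores`, `groups`, `trg_correlation` (or `NULL`),
#'   and `endpoints` (per-endpoint `survival_comparison`).
#' @export
run_prognosis_experiment <- function(bundle, classifier, out_dir = NULL,
                                     values_are_log2 = TRUE, align = TRUE) {
  scores <-
    if (inherits(classifier, "trained_svm")) {
      em <- bundle$expression
      if (align && !is.null(classifier$reference))
        em <- align_to_reference(em, classifier$reference)
      svm_decision_values(classifier, em)
    } else if (inherits(classifier, "ratio_score")) {
      compute_ratio_score(bundle$expression, classifier,
                          values_are_log2 = values_are_log2)
    } else {
      s <- as.numeric(classifier)
      names(s) <- if (!is.null(names(classifier))) names(classifier)
                  else bundle$expression$sample_ids
      s[bundle$expression$sample_ids]
    }
  ann <- bundle$annotation
  trg_cor <- if (sum(is.finite(ann$trg_percent)) >= 3 &&
                 sd(ann$trg_percent, na.rm = TRUE) > 0)
    spearman_rho(scores, ann$trg_percent)
  groups <- median_split(scores)
  endpoints <- list()
  for (ep in c("os", "dfs")) {
    tm <- ann[[paste0(ep, "_time")]]; ev <- ann[[paste0(ep, "_event")]]
    ok <- is.finite(tm) & is.finite(ev)
    if (!any(ok)) next
    if (sum(ev[ok]) < 1) stop("no events observed for endpoint '", ep, "'")
    endpoints[[ep]] <- logrank_test(groups[ok], tm[ok], ev[ok])
  }
  if (!length(endpoints)) stop("bundle carries no survival follow-up")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(data.frame(sample_id = names(scores), score = scores,
                           group = groups),
                file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_json_artifact(
      lapply(endpoints, function(e)
        list(chi_square = e$chi_square, p_value = e$p_value,
             km_curves = e$km_curves)),
      file.path(out_dir, "km.json"))
  }
  list(scores = scores, groups = groups, trg_correlation = trg_cor,
       endpoints = endpoints)
}
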