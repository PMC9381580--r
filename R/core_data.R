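#' pcrsig: gene-expression classifiers of pathological complete response
#'
#' Tools to discover and apply pretreatment transcriptomic classifiers of
#' pathological complete response (pCR) to neoadjuvant chemoradiotherapy in
#' rectal cancer: resampled hill-climbing feature selection under a
#' zero-false-positive sensitivity objective, a frozen linear SVM with
#' reference-anchored quantile normalization, a normalization-free
#' ratio-of-sums score classifier, and score-based survival stratification.
#'
#' @keywords internal
#' @importFrom stats ave median pbinom pchisq pt rexp rnorm runif sd
#'   uniroot var cor setNames
#' @importFrom utils read.delim write.table head
"_PACKAGE"

# ---------------------------------------------------------------------------
# ExpressionMatrix
# ---------------------------------------------------------------------------

#' Construct an expression matrix object
#'
#' A light container for a log2 (or linear) intensity matrix with transcript
#' (row) and sample (column) annotation. Rows are probes/transcripts, columns
#' are samples.
#'
#' @param values numeric matrix, transcripts x samples, all finite.
#' @param probe_ids character vector of unique row identifiers.
#' @param gene_symbols character vector of per-row gene symbols (aliases
#'   allowed, duplicates allowed).
#' @param sample_ids character vector of unique column identifiers.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probe_ids, gene_symbols, sample_ids) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one row and one column")
  if (length(probe_ids) != nrow(values))
    stop("probe_ids length does not match row count")
  if (length(gene_symbols) != nrow(values))
    stop("gene_symbols length does not match row count")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match column count")
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop("duplicate probe_id: ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at row %d ('%s'), column %d ('%s')",
                 bad[1L], probe_ids[bad[1L]], bad[2L], sample_ids[bad[2L]]))
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(
    list(values = values,
         probe_ids = as.character(probe_ids),
         gene_symbols = as.character(gene_symbols),
         sample_ids = as.character(sample_ids)),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d transcripts x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expected layout: tab-separated, UTF-8, "." decimal separator; header row of
#' sample ids; first two columns `probe_id` and `gene_symbol`, remaining
#' columns numeric intensities.
#'
#' @param path file path.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 3L)
    stop("expression TSV needs probe_id, gene_symbol and >= 1 sample column")
  sample_ids <- colnames(df)[-(1:2)]
  vals <- matrix(NA_real_, nrow(df), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 2L]]))
    bad <- which(is.na(v) & !is.na(df[[j + 2L]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   df[[j + 2L]][bad[1L]], bad[1L], sample_ids[j]))
    vals[, j] <- v
  }
  expression_matrix(vals, df[[1L]], df[[2L]], sample_ids)
}

#' Write an expression matrix to TSV
#'
#' Values are serialized with 15 significant digits so that a
#' write/read round trip preserves identifiers exactly and values to at least
#' 12 significant digits.
#'
#' @param mat an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(probe_id = mat$probe_ids,
                   gene_symbol = mat$gene_symbols,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(mat$sample_ids))
    df[[mat$sample_ids[j]]] <- sprintf("%.15g", mat$values[, j])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SampleAnnotation
# ---------------------------------------------------------------------------

#' Construct a per-sample clinical annotation table
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param trg_percent tumour regression grade in percent (0-100) or `NA`.
#' @param trg_ordinal ordinal regression grade (e.g. Dworak 0-4) or `NA`.
#' @param cohort_label free-text cohort name.
#' @param os_time,os_event overall-survival follow-up time (>= 0) and event
#'   indicator (0/1), or `NA`.
#' @param dfs_time,dfs_event disease-free-survival follow-up, same conventions.
#' @param sex,age optional covariates.
#' @return A data.frame with class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, trg_percent = NA_real_,
                              trg_ordinal = NA_real_, cohort_label = "cohort",
                              os_time = NA_real_, os_event = NA_real_,
                              dfs_time = NA_real_, dfs_event = NA_real_,
                              sex = NA_character_, age = NA_real_) {
  n <- length(sample_id)
  ann <- data.frame(sample_id = as.character(sample_id),
                    trg_percent = rep_len(as.numeric(trg_percent), n),
                    trg_ordinal = rep_len(as.numeric(trg_ordinal), n),
                    cohort_label = rep_len(as.character(cohort_label), n),
                    os_time = rep_len(as.numeric(os_time), n),
                    os_event = rep_len(as.numeric(os_event), n),
                    dfs_time = rep_len(as.numeric(dfs_time), n),
                    dfs_event = rep_len(as.numeric(dfs_event), n),
                    sex = rep_len(as.character(sex), n),
                    age = rep_len(as.numeric(age), n),
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

validate_annotation <- function(ann) {
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation")
  tp <- ann$trg_percent
  if (any(!is.na(tp) & (tp < 0 | tp > 100)))
    stop("trg_percent must lie in [0, 100]")
  for (ev in c("os_event", "dfs_event")) {
    e <- ann[[ev]]
    if (any(!is.na(e) & !(e %in% c(0, 1))))
      stop(ev, " must be 0 or 1")
  }
  for (tm in c("os_time", "dfs_time")) {
    t <- ann[[tm]]
    if (any(!is.na(t) & t < 0)) stop(tm, " must be >= 0")
  }
  invisible(ann)
}

#' Read a sample annotation TSV
#'
#' One row per sample, columns as in [sample_annotation()]; empty cells are
#' missing values.
#'
#' @param path file path.
#' @return A `sample_annotation` data.frame.
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("", "NA"))
  do.call(sample_annotation, df[intersect(names(df), names(formals(sample_annotation)))])
}

# ---------------------------------------------------------------------------
# Response labels
# ---------------------------------------------------------------------------

#' Derive response labels from tumour regression grading
#'
#' A sample is `positive` (pCR) when its TRG is exactly the complete-response
#' threshold (100 percent: no viable tumour cells), `negative` (poor response)
#' when its TRG is strictly below the poor-response threshold (45 percent by
#' default), `intermediate` in between, and `unknown` when the percent grade
#' is missing and no ordinal mapping applies.
#'
#' @param annotation a `sample_annotation` data.frame.
#' @param complete_threshold TRG percent defining complete response (100).
#' @param poor_threshold TRG percent strictly below which response is poor (45).
#' @param ordinal_map optional named vector mapping ordinal grades to labels,
#'   e.g. `c("4" = "positive")` for Dworak grade 4 = complete regression; used
#'   only when `trg_percent` is missing.
#' @return A data.frame (`sample_id`, `label`) with class `response_labels`;
#'   labels are one of positive/negative/intermediate/unknown.
#' @export
derive_labels <- function(annotation, complete_threshold = 100,
                          poor_threshold = 45, ordinal_map = NULL) {
  stopifnot(poor_threshold > 0, poor_threshold <= complete_threshold,
            complete_threshold <= 100)
  tp <- annotation$trg_percent
  lab <- rep("unknown", nrow(annotation))
  has <- !is.na(tp)
  lab[has & tp >= complete_threshold] <- "positive"
  lab[has & tp < poor_threshold] <- "negative"
  lab[has & tp >= poor_threshold & tp < complete_threshold] <- "intermediate"
  if (!is.null(ordinal_map)) {
    to <- annotation$trg_ordinal
    idx <- which(!has & !is.na(to) & as.character(to) %in% names(ordinal_map))
    lab[idx] <- unname(ordinal_map[as.character(to[idx])])
  }
  out <- data.frame(sample_id = annotation$sample_id, label = lab,
                    stringsAsFactors = FALSE)
  class(out) <- c("response_labels", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Cohort bundle
# ---------------------------------------------------------------------------

#' Bundle expression, annotation and labels for one cohort
#'
#' @param expression an [expression_matrix()].
#' @param annotation a `sample_annotation` data.frame.
#' @param labels a `response_labels` data.frame; derived from `annotation`
#'   when omitted.
#' @return A list with class `cohort_bundle`; the three components cover an
#'   identical sample set, aligned to the expression column order.
#' @export
cohort_bundle <- function(expression, annotation, labels = NULL) {
  if (is.null(labels)) labels <- derive_labels(annotation)
  ids <- expression$sample_ids
  if (!setequal(ids, annotation$sample_id) || !setequal(ids, labels$sample_id))
    stop("expression, annotation and labels must cover the same samples")
  annotation <- annotation[match(ids, annotation$sample_id), , drop = FALSE]
  labels <- labels[match(ids, labels$sample_id), , drop = FALSE]
  rownames(annotation) <- rownames(labels) <- NULL
  structure(list(expression = expression, annotation = annotation,
                 labels = labels),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  tab <- table(factor(x$labels$label,
                      c("positive", "negative", "intermediate", "unknown")))
  cat(sprintf("cohort_bundle: %d transcripts x %d samples (%s)\n",
              nrow(x$expression$values), ncol(x$expression$values),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Restrict a cohort bundle to a subset of samples
#'
#' @param bundle a `cohort_bundle`.
#' @param sample_ids samples to keep (order preserved as given).
#' @return A `cohort_bundle` on the requested samples.
#' @export
subset_samples <- function(bundle, sample_ids) {
  idx <- match(sample_ids, bundle$expression$sample_ids)
  if (anyNA(idx)) stop("unknown sample id: ",
                       paste(sample_ids[is.na(idx)], collapse = ", "))
  em <- bundle$expression
  em2 <- expression_matrix(em$values[, idx, drop = FALSE], em$probe_ids,
                           em$gene_symbols, em$sample_ids[idx])
  cohort_bundle(em2,
                bundle$annotation[match(sample_ids, bundle$annotation$sample_id), ,
                                  drop = FALSE],
                bundle$labels[match(sample_ids, bundle$labels$sample_id), ,
                              drop = FALSE])
}

#' Keep only extreme responders (positive and negative labels)
#'
#' Convenience for the 32 + 32 extreme-response training design.
#'
#' @param bundle a `cohort_bundle`.
#' @return A `cohort_bundle` containing only positive/negative samples.
#' @export
extreme_responders <- function(bundle) {
  keep <- bundle$labels$sample_id[bundle$labels$label %in% c("positive", "negative")]
  if (!length(keep)) stop("no positive/negative samples in bundle")
  subset_samples(bundle, keep)
}

# ---------------------------------------------------------------------------
# Signature gene sets and aliasing
# ---------------------------------------------------------------------------

#' Gene-symbol alias map for the 21-transcript signature
#'
#' The published ratio-score formula uses legacy symbols while the signature
#' table uses current HGNC names; this map reconciles them
#' (legacy name -> current name).
#'
#' @return Named character vector mapping legacy to current symbols.
#' @export
gene_alias_map <- function() {
  c(KIAA1598 = "SHTN1",
    C19orf51 = "DNAAF3",
    C20orf26 = "CFAP61",
    CASC5    = "KNL1")
}

canonical_symbol <- function(symbols, alias_map = gene_alias_map()) {
  hit <- symbols %in% names(alias_map)
  symbols[hit] <- unname(alias_map[symbols[hit]])
  symbols
}

#' The 21-transcript pCR signature
#'
#' The transcript list of the published classifier: gene symbol and the
#' Agilent probe carrying it.
#'
#' @return data.frame with columns `gene_symbol`, `probe_id`.
#' @export
signature_21 <- function() {
  data.frame(
    gene_symbol = c("CGREF1", "FZD10", "ASPM", "SHTN1", "CCNB1", "CXCL10",
                    "CFAP61", "XPO1", "BRCA1", "TMPO", "CASC5", "FANCM",
                    "BLM", "HOMER1", "TNPO3", "CENPL", "CSPP1", "STARD3",
                    "DNAAF3", "MCM5", "TSNAX"),
    probe_id = c("A_33_P3281850", "A_23_P203972", "A_23_P52017",
                 "A_23_P202587", "A_23_P122197", "A_24_P303091", "A_32_P4262",
                 "A_23_P40078", "A_23_P207400", "A_23_P325040", "A_23_P100127",
                 "A_32_P106732", "A_23_P88630", "A_33_P3372257",
                 "A_33_P3370132", "A_23_P126120", "A_23_P71537",
                 "A_33_P3246804", "A_33_P3286349", "A_23_P132277",
                 "A_24_P148151"),
    stringsAsFactors = FALSE)
}

#' Subset an expression matrix to a gene signature
#'
#' Symbols in both the request and the matrix are first passed through the
#' alias map, then matched; rows are returned in `gene_list` order. When a
#' symbol is carried by several probes the probes are collapsed to their
#' per-sample mean and the row is re-identified by the symbol.
#'
#' @param mat an [expression_matrix()].
#' @param gene_list character vector of requested gene symbols.
#' @param alias_map legacy-to-current symbol map; see [gene_alias_map()].
#' @param missing what to do when a requested gene is absent: `"fail"` (error),
#'   `"drop"` (warn and omit), or `"impute-reference-mean"` (warn and fill the
#'   row with the across-matrix mean value).
#' @return An [expression_matrix()] with one row per resolved gene.
#' @export
subset_to_signature <- function(mat, gene_list,
                                alias_map = gene_alias_map(),
                                missing = c("fail", "drop", "impute-reference-mean")) {
  missing <- match.arg(missing)
  want <- canonical_symbol(as.character(gene_list), alias_map)
  have <- canonical_symbol(mat$gene_symbols, alias_map)
  absent <- setdiff(want, have)
  if (length(absent)) {
    msg <- paste("genes not found in matrix:", paste(absent, collapse = ", "))
    if (missing == "fail") stop(msg)
    warning(msg, " (policy: ", missing, ")")
  }
  rows <- list(); probes <- character(0); syms <- character(0)
  ref_mean <- mean(mat$values)
  for (g in want) {
    idx <- which(have == g)
    if (length(idx) == 0L) {
      if (missing == "impute-reference-mean") {
        rows[[length(rows) + 1L]] <- rep(ref_mean, ncol(mat$values))
        probes <- c(probes, paste0("imputed:", g)); syms <- c(syms, g)
      }
      next
    }
    if (length(idx) == 1L) {
      rows[[length(rows) + 1L]] <- mat$values[idx, ]
      probes <- c(probes, mat$probe_ids[idx])
    } else {
      rows[[length(rows) + 1L]] <- colMeans(mat$values[idx, , drop = FALSE])
      probes <- c(probes, paste0("mean:", g))
    }
    syms <- c(syms, g)
  }
  if (!length(rows)) {
    out <- structure(
      list(values = matrix(numeric(0), 0L, ncol(mat$values),
                           dimnames = list(NULL, mat$sample_ids)),
           probe_ids = character(0), gene_symbols = character(0),
           sample_ids = mat$sample_ids),
      class = "expression_matrix")
    return(out)
  }
  expression_matrix(do.call(rbind, rows), probes, syms, mat$sample_ids)
}
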