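# Classifier evaluation: ROC/AUC, the sensitivity-at-zero-FPR statistic that
# is the pipeline's primary deployment metric, precision-recall, rank
# correlation, and survival comparison (Kaplan-Meier, log-rank).

check_two_classes <- function(labels) {
  pos <- labels == "positive"
  if (!any(pos) || !any(!pos))
    stop("both classes must be present")
  pos
}

as_binary_labels <- function(labels) {
  # accept logical, 0/1 numeric or character/factor labels
  if (is.logical(labels)) return(ifelse(labels, "positive", "negative"))
  if (is.numeric(labels)) return(ifelse(labels > 0, "positive", "negative"))
  as.character(labels)
}

#' Sensitivity at zero false-positive rate
#'
#' The largest true-positive rate achievable by any score threshold that
#' admits no negative: the fraction of positives scoring strictly above the
#' best-scoring negative. A positive tied with the best negative does not
#' count, so the statistic is a guarantee — at the implied threshold no
#' negative is ever called positive.
#'
#' @param scores numeric classification scores (higher = more positive).
#' @param labels class labels; `"positive"` is the positive class (logical
#'   and 0/1 vectors are also accepted).
#' @return Fraction in \[0, 1\].
#' @export
sensitivity_at_zero_fpr <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  pos <- check_two_classes(labels)
  sum(scores[pos] > max(scores[!pos])) / sum(pos)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the fraction of positive-negative
#' pairs in which the positive outscores the negative, ties counted one half.
#'
#' @inheritParams sensitivity_at_zero_fpr
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  pos <- check_two_classes(labels)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve
#'
#' One point per distinct threshold (descending through the observed scores)
#' plus the (0, 0) and (1, 1) endpoints; the trapezoidal integral of the
#' curve equals [auc()].
#'
#' @inheritParams sensitivity_at_zero_fpr
#' @return data.frame with columns `fpr`, `tpr`, both non-decreasing.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  pos <- check_two_classes(labels)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # advance through tie blocks so each distinct score yields one point
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(p)[last]; fp <- cumsum(!p)[last]
  data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

#' Precision-recall curve
#'
#' One point per distinct threshold, descending; starts at (0, 1) by
#' convention and ends at recall 1 with precision = prevalence.
#'
#' @inheritParams sensitivity_at_zero_fpr
#' @return data.frame with columns `recall`, `precision`.
#' @export
precision_recall_curve <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  pos <- check_two_classes(labels)
  n_pos <- sum(pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(p)[last]; n_called <- last
  data.frame(recall = c(0, tp / n_pos), precision = c(1, tp / n_called))
}

#' Trapezoidal area under a curve
#'
#' @param x,y coordinates with `x` non-decreasing.
#' @return The trapezoidal integral.
#' @export
trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Full evaluation report for a score vector
#'
#' @inheritParams sensitivity_at_zero_fpr
#' @return A list with class `eval_report`: `auc`, `sens_at_zero_fpr`,
#'   `roc_points`, `pr_points`, `n_positive`, `n_negative`.
#' @export
eval_report <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  pos <- check_two_classes(labels)
  structure(list(auc = auc(scores, labels),
                 sens_at_zero_fpr = sensitivity_at_zero_fpr(scores, labels),
                 roc_points = roc_curve(scores, labels),
                 pr_points = precision_recall_curve(scores, labels),
                 n_positive = sum(pos), n_negative = sum(!pos)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: AUC = %.3f, sensitivity at zero FPR = %.3f (%d pos / %d neg)\n",
              x$auc, x$sens_at_zero_fpr, x$n_positive, x$n_negative))
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of tie-averaged ranks; the p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3; pairs with missing values
#'   are dropped.
#' @return list with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need equal-length vectors with >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("rank correlation undefined for a constant vector")
  rho <- cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `survival`;
#'   one row per distinct event time, survival non-increasing from 1.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  et <- sort(unique(times[events == 1]))
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  data.frame(time = et, n_risk = n_risk, n_event = n_event,
             survival = cumprod(1 - n_event / n_risk))
}

#' Two-group log-rank test
#'
#' Implements the hypergeometric observed-minus-expected construction: at
#' each distinct event time the expected events in group 1 are
#' `d * n1 / n` and the variance is `d (n1/n)(1 - n1/n)(n - d)/(n - 1)`;
#' the statistic `(O1 - E1)^2 / V` is chi-square on 1 degree of freedom.
#'
#' @param groups two-level group labels.
#' @param times,events as in [km_estimate()].
#' @return A list with class `survival_comparison`: `chi_square`, `p_value`,
#'   `observed`, `expected` (per group) and `km_curves` (per-group
#'   Kaplan-Meier step functions).
#' @export
logrank_test <- function(groups, times, events) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("logrank_test requires exactly two groups")
  if (sum(events) < 1) stop("no events observed")
  g1 <- groups == lev[1L]
  et <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- if (v > 0) pchisq(chi, df = 1, lower.tail = FALSE) else 1
  km <- lapply(lev, function(l) km_estimate(times[groups == l], events[groups == l]))
  names(km) <- lev
  structure(list(chi_square = chi, p_value = p,
                 observed = setNames(c(o1, sum(events) - o1), lev),
                 expected = setNames(c(e1, sum(events) - e1), lev),
                 km_curves = km),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.3f (1 df), p = %.3g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Split samples at the median score
#'
#' Samples strictly above the median go to the high group; samples at or
#' below the median go to the low group (the declared tie rule). If all
#' scores are equal everything is low, with a warning.
#'
#' @param scores numeric vector, length >= 2.
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
median_split <- function(scores) {
  stopifnot(length(scores) >= 2)
  med <- median(scores)
  out <- ifelse(scores > med, "high", "low")
  if (all(out == "low"))
    warning("all scores at or below the median; every sample assigned 'low'")
  out
}
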