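# Evaluation statistics: per-class diagnostic metrics, rank-based AUC,
# exact binomial confidence intervals, Passing-Bablok method-comparison
# regression, case-level status tables and dilution error analysis.

#' Populations reported individually in metric tables
#' @keywords internal
reported_populations <- function() {
  c("CLL_cells", "B_cells", "hematogones", "plasma_cells", "T_cells",
    "aggregates", "debris", "Other")
}

#' One-vs-rest confusion counts per population
#'
#' Counts TP/TN/FP/FN for each reported population. With
#' `group_other = TRUE` (default), basophils/dendritic cells, blasts,
#' erythroblasts, granulocytes, monocytes, NK cells and unknown events
#' are merged into a single "Other" category before counting, as in the
#' reported tables; otherwise all 14 classes are reported individually.
#'
#' @param truth,predicted Character vectors of event labels, equal
#'   length.
#' @param group_other Merge minor classes into Other.
#' @return Data frame with columns `population`, `TP`, `TN`, `FP`, `FN`;
#'   for every row TP+TN+FP+FN equals the number of events.
#' @export
confusion <- function(truth, predicted, group_other = TRUE) {
  truth <- validate_labels(truth)
  predicted <- validate_labels(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted labels differ in length", call. = FALSE)
  }
  if (group_other) {
    other <- other_cell_classes()
    truth[truth %in% other] <- "Other"
    predicted[predicted %in% other] <- "Other"
    pops <- reported_populations()
  } else {
    pops <- cll_classes()
  }
  n <- length(truth)
  do.call(rbind, lapply(pops, function(p) {
    tp <- sum(truth == p & predicted == p)
    fp <- sum(truth != p & predicted == p)
    fn <- sum(truth == p & predicted != p)
    data.frame(population = p, TP = tp, TN = n - tp - fp - fn,
               FP = fp, FN = fn, stringsAsFactors = FALSE)
  }))
}

#' Diagnostic metrics from confusion counts
#'
#' Computes accuracy, sensitivity (recall), specificity, PPV (precision),
#' NPV and F1 as dimensionless ratios:
#' accuracy = (TP+TN)/N, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN),
#' F1 = 2TP/(2TP+FP+FN). Ratios with a zero denominator are reported as
#' `NA` rather than silently inflated.
#'
#' @param counts Data frame with columns `TP`, `TN`, `FP`, `FN` (and
#'   optionally `population`), e.g. from [confusion()].
#' @return The input with metric columns appended.
#' @export
class_metrics <- function(counts) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  with_na <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, tn, fp, fn) < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  counts$accuracy <- with_na(tp + tn, tp + tn + fp + fn)
  counts$sensitivity <- with_na(tp, tp + fn)
  counts$specificity <- with_na(tn, tn + fp)
  counts$ppv <- with_na(tp, tp + fp)
  counts$npv <- with_na(tn, tn + fn)
  counts$f1 <- with_na(2 * tp, 2 * tp + fp + fn)
  counts
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile formulation: lower bound
#' `qbeta(alpha/2, k, n-k+1)` (0 when k = 0), upper bound
#' `qbeta(1-alpha/2, k+1, n-k)` (1 when k = n).
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)` on the proportion scale.
#' @export
#' @examples
#' exact_binomial_ci(25, 25)  # lower bound 0.863
exact_binomial_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n, level > 0, level < 1)
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Case-level MRD status 2x2 table and metrics
#'
#' Cross-tabulates automated versus expert MRD status and derives
#' accuracy, sensitivity, specificity, PPV and NPV (as percents) with
#' exact 95% confidence intervals, treating the expert designation as
#' ground truth.
#'
#' @param dnn_status,expert_status Character vectors
#'   (`"MRD_positive"`/`"MRD_negative"`), aligned by case.
#' @param level Confidence level.
#' @return List of class `mrd_status_table` with `table` (2x2 matrix,
#'   rows = DNN, cols = expert) and `metrics` (data frame: metric,
#'   percent estimate, CI bounds, k, n).
#' @export
status_table <- function(dnn_status, expert_status, level = 0.95) {
  stopifnot(length(dnn_status) == length(expert_status))
  lv <- c("MRD_negative", "MRD_positive")
  stopifnot(all(dnn_status %in% lv), all(expert_status %in% lv))
  tp <- sum(dnn_status == "MRD_positive" & expert_status == "MRD_positive")
  tn <- sum(dnn_status == "MRD_negative" & expert_status == "MRD_negative")
  fp <- sum(dnn_status == "MRD_positive" & expert_status == "MRD_negative")
  fn <- sum(dnn_status == "MRD_negative" & expert_status == "MRD_positive")
  status_table_from_counts(tp, tn, fp, fn, level)
}

#' @rdname status_table
#' @param tp,tn,fp,fn Case counts of the 2x2 matrix (DNN vs expert).
#' @export
status_table_from_counts <- function(tp, tn, fp, fn, level = 0.95) {
  tab <- matrix(as.numeric(c(tn, fp, fn, tp)), nrow = 2,
                dimnames = list(DNN = c("MRD_negative", "MRD_positive"),
                                expert = c("MRD_negative", "MRD_positive")))
  prop <- function(metric, k, n) {
    if (n == 0) {
      return(data.frame(metric = metric, percent = NA_real_,
                        lower = NA_real_, upper = NA_real_, k = k, n = n))
    }
    ci <- exact_binomial_ci(k, n, level)
    data.frame(metric = metric, percent = 100 * k / n,
               lower = 100 * ci[["lower"]], upper = 100 * ci[["upper"]],
               k = k, n = n, stringsAsFactors = FALSE)
  }
  metrics <- rbind(
    prop("accuracy", tp + tn, tp + tn + fp + fn),
    prop("sensitivity", tp, tp + fn),
    prop("specificity", tn, tn + fp),
    prop("ppv", tp, tp + fp),
    prop("npv", tn, tn + fn)
  )
  structure(list(table = tab, metrics = metrics, level = level),
            class = "mrd_status_table")
}

#' @export
print.mrd_status_table <- function(x, ...) {
  print(x$table)
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("%-12s %5.1f%% (%s CI: %.1f-%.1f%%)\n", m$metric[i],
                m$percent[i], paste0(100 * x$level, "%"),
                m$lower[i], m$upper[i]))
  }
  invisible(x)
}

#' Rank-based (Mann-Whitney) area under the ROC curve
#'
#' Computed from the per-event class score via midranks, so ties are
#' averaged: AUC = (R1 - n1(n1+1)/2) / (n1 n0), with R1 the rank sum of
#' the positive scores.
#'
#' @param scores Numeric score per event (e.g. the class's softmax
#'   probability).
#' @param truth Logical (or 0/1) one-vs-rest truth per event; both
#'   classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Passing-Bablok method-comparison regression
#'
#' The original rank-based procedure for positively correlated methods:
#' the slope is the shifted median of all pairwise slopes
#' `S_ij = (y_j - y_i)/(x_j - x_i)` — pairs with identical points are
#' dropped, slopes exactly equal to -1 are discarded, and the median
#' index is offset by `K`, the number of slopes below -1. A tied pair
#' with equal x and different y contributes an infinite slope with the
#' sign of the y difference. For an even slope count the two central
#' (offset) order statistics are averaged. The intercept is
#' `median(y - slope * x)`. Confidence bounds come from the rank-order
#' normal approximation; intercept bounds reuse the slope bounds.
#'
#' @param x Reference (expert) values.
#' @param y Test (automated) values.
#' @param level Confidence level, default 0.95.
#' @return A list of class `PBRegression`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `n`, `n_slopes`.
#' @export
passing_bablok <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("degenerate input: all x values identical", call. = FALSE)
  }
  pairs <- utils::combn(n, 2)
  dx <- x[pairs[2, ]] - x[pairs[1, ]]
  dy <- y[pairs[2, ]] - y[pairs[1, ]]
  keep <- !(dx == 0 & dy == 0)
  dx <- dx[keep]; dy <- dy[keep]
  s <- ifelse(dx == 0, sign(dy) * Inf, dy / dx)
  s <- s[s != -1]
  ns <- length(s)
  if (ns == 0) stop("no valid pairwise slopes", call. = FALSE)
  s <- sort(s)  # Inf sorts last, -Inf first
  k <- sum(s < -1)
  shifted_med <- function(sorted, offset) {
    m <- length(sorted)
    if (m %% 2 == 1) sorted[(m + 1) / 2 + offset]
    else mean(sorted[m / 2 + offset + 0:1])
  }
  slope <- shifted_med(s, k)

  z <- stats::qnorm(1 - (1 - level) / 2)
  cq <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((ns - cq) / 2)
  m2 <- ns - m1 + 1
  lo_i <- max(1, m1 + k); hi_i <- min(ns, m2 + k)
  slope_ci <- c(s[lo_i], s[hi_i])
  intercept <- stats::median(y - slope * x)
  intercept_ci <- c(stats::median(y - slope_ci[2] * x),
                    stats::median(y - slope_ci[1] * x))
  structure(
    list(slope = slope, intercept = intercept, slope_ci = slope_ci,
         intercept_ci = intercept_ci, n = n, n_slopes = ns,
         level = level),
    class = "PBRegression"
  )
}

#' @export
print.PBRegression <- function(x, ...) {
  cat(sprintf("Passing-Bablok regression (n = %d)\n", x$n))
  cat(sprintf("  slope     %.4f (%.0f%% CI: %.4f-%.4f)\n", x$slope,
              100 * x$level, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.4f (%.0f%% CI: %.4f-%.4f)\n", x$intercept,
              100 * x$level, x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors (n >= 2, nonzero variances).
#' @return Correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Serial-dilution error analysis
#'
#' For each dilution sample, compares automated versus expert CLL counts:
#' the proportionate error `100 (dnn - expert) / expert` (percent) when
#' the expert count is >= 1000 events, otherwise the absolute delta
#' `dnn - expert` (events). The %WBC comparison is always the absolute
#' difference.
#'
#' @param expert_count,dnn_count CLL MRD event counts (non-negative).
#' @param expert_pct,dnn_pct Optional CLL MRD %WBC values.
#' @return Data frame with `error` (numeric), `error_type`
#'   (`"proportionate"`/`"absolute"`) and, when percents are given,
#'   `abs_error_pct_wbc = dnn_pct - expert_pct`.
#' @export
dilution_errors <- function(expert_count, dnn_count,
                            expert_pct = NULL, dnn_pct = NULL) {
  stopifnot(length(expert_count) == length(dnn_count),
            all(expert_count >= 0), all(dnn_count >= 0))
  proportionate <- expert_count >= 1000
  out <- data.frame(
    expert_count = expert_count, dnn_count = dnn_count,
    error = ifelse(proportionate,
                   100 * (dnn_count - expert_count) / expert_count,
                   dnn_count - expert_count),
    error_type = ifelse(proportionate, "proportionate", "absolute"),
    stringsAsFactors = FALSE
  )
  if (!is.null(expert_pct) && !is.null(dnn_pct)) {
    stopifnot(length(expert_pct) == length(expert_count),
              length(dnn_pct) == length(expert_count))
    out$expert_pct_wbc <- expert_pct
    out$dnn_pct_wbc <- dnn_pct
    out$abs_error_pct_wbc <- dnn_pct - expert_pct
  }
  out
}
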