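# Hybrid F-DNN/L-DNN case-level decision logic: MRD status designation
# and quantification against the aggregate/debris-free WBC denominator.

#' Hybrid cascade configuration
#'
#' @param low_count_threshold F-DNN CLL event count below which the case
#'   is handed to the L-DNN (default 1000).
#' @param positivity_threshold Minimum CLL event count reliably defining
#'   an abnormal population; at or above it the case is MRD-positive
#'   (default 20).
#' @param wbc_exclusion_classes Classes removed from the WBC denominator
#'   (default aggregates and debris).
#' @param normalization_wbc WBC count every case is normalized to
#'   (default 1e6, the typical WBC retained after removing time errors,
#'   aggregates and debris).
#' @return A list of class `HybridConfig`.
#' @export
hybrid_config <- function(low_count_threshold = 1000L,
                          positivity_threshold = 20L,
                          wbc_exclusion_classes = c("aggregates", "debris"),
                          normalization_wbc = 1e6) {
  if (!(positivity_threshold < low_count_threshold)) {
    stop("positivity threshold must be below the low-count threshold",
         call. = FALSE)
  }
  stopifnot(positivity_threshold >= 0, normalization_wbc > 0)
  structure(
    list(low_count_threshold = low_count_threshold,
         positivity_threshold = positivity_threshold,
         wbc_exclusion_classes = wbc_exclusion_classes,
         normalization_wbc = normalization_wbc),
    class = "HybridConfig"
  )
}

#' Count events of one class
#'
#' @param labels Character vector of event labels.
#' @param class Class name.
#' @return Integer count.
#' @export
count_class <- function(labels, class) {
  sum(validate_labels(labels) == class)
}

#' WBC denominator of a labeled case
#'
#' Total events minus those labeled with an excluded class (aggregates and
#' debris by default). Unknown-labeled events count toward the
#' denominator.
#'
#' @param labels Character vector of event labels.
#' @param cfg A [hybrid_config()].
#' @return Integer count (possibly 0; downstream quantities guard).
#' @export
wbc_denominator <- function(labels, cfg = hybrid_config()) {
  labels <- validate_labels(labels)
  sum(!labels %in% cfg$wbc_exclusion_classes)
}

#' Designate MRD status from a CLL event count
#'
#' MRD-positive if and only if the count reaches the positivity threshold
#' (20 events by default).
#'
#' @param cll_events Non-negative CLL event count.
#' @param cfg A [hybrid_config()].
#' @return `"MRD_positive"` or `"MRD_negative"`.
#' @export
designate_status <- function(cll_events, cfg = hybrid_config()) {
  stopifnot(cll_events >= 0)
  if (cll_events >= cfg$positivity_threshold) "MRD_positive"
  else "MRD_negative"
}

#' Analytic sensitivity implied by the positivity rule
#'
#' The smallest reportable MRD level: the positivity threshold over the
#' normalization WBC count, as a percent. Defaults give
#' 100 * 20 / 1e6 = 0.002%.
#'
#' @param cfg A [hybrid_config()].
#' @return Percent (numeric scalar).
#' @export
analytic_sensitivity <- function(cfg = hybrid_config()) {
  100 * cfg$positivity_threshold / cfg$normalization_wbc
}

#' Upsample a test-split count to a normalized whole-case count
#'
#' Test events are only ~10% of a case, so case-level comparisons express
#' the CLL count per normalization WBC (1 million by default):
#' `normalization_wbc * count / wbc`.
#'
#' @param count_in_test_split CLL events observed in the split.
#' @param wbc_in_test_split WBC denominator of the same split (> 0).
#' @param cfg A [hybrid_config()].
#' @return Normalized count (events per `normalization_wbc` WBC).
#' @export
upsample_to_case <- function(count_in_test_split, wbc_in_test_split,
                             cfg = hybrid_config()) {
  if (wbc_in_test_split <= 0) {
    stop("WBC denominator must be positive", call. = FALSE)
  }
  cfg$normalization_wbc * count_in_test_split / wbc_in_test_split
}

# Quantities and status from a final label vector.
.mrd_from_labels <- function(case_id, labels, deciding, cfg) {
  cll <- sum(labels == "CLL_cells")
  wbc <- wbc_denominator(labels, cfg)
  structure(
    list(case_id = case_id,
         cll_events = cll,
         wbc_events = wbc,
         pct_wbc = if (wbc > 0) 100 * cll / wbc else NA_real_,
         normalized_count = if (wbc > 0)
           cfg$normalization_wbc * cll / wbc else NA_real_,
         status = designate_status(cll, cfg),
         deciding_network = deciding,
         labels = labels),
    class = "MRDResult"
  )
}

#' Hybrid F-DNN/L-DNN classification of a case
#'
#' The F-DNN classifies all events first. If its CLL count is at or above
#' the low-count threshold (1000), the F-DNN labels are final. Otherwise
#' the L-DNN re-classifies all events of the case and its labels are
#' final. MRD status, %WBC and the normalized count are computed from the
#' deciding network's labels; a zero WBC denominator leaves the
#' quantities undefined (NA) while status still follows the raw count.
#'
#' @param case A [case_sample()] (truth labels not required).
#' @param f_model,l_model Trained F-DNN and L-DNN models.
#' @param cfg A [hybrid_config()].
#' @return An `MRDResult`: case id, CLL event count, WBC denominator,
#'   `pct_wbc`, `normalized_count`, `status`, `deciding_network`
#'   (`"F"` or `"L"`), and the final per-event `labels`.
#' @export
hybrid_classify <- function(case, f_model, l_model, cfg = hybrid_config()) {
  stopifnot(inherits(case, "CaseSample"))
  f_labels <- predict_events(f_model, case$events)$labels
  f_cll <- sum(f_labels == "CLL_cells")
  if (f_cll >= cfg$low_count_threshold) {
    res <- .mrd_from_labels(case$case_id, f_labels, "F", cfg)
  } else {
    l_labels <- predict_events(l_model, case$events)$labels
    res <- .mrd_from_labels(case$case_id, l_labels, "L", cfg)
  }
  res$f_cll_events <- f_cll
  res
}

#' @export
print.MRDResult <- function(x, ...) {
  cat("MRDResult", x$case_id, "-", x$status,
      sprintf("(%s-DNN)\n", x$deciding_network))
  cat(sprintf("  CLL events: %d / WBC %d (%.4f%% WBC, %.1f per 1e6)\n",
              x$cll_events, x$wbc_events,
              if (is.na(x$pct_wbc)) NaN else x$pct_wbc,
              if (is.na(x$normalized_count)) NaN else x$normalized_count))
  invisible(x)
}

#' Tabulate MRD results
#'
#' @param results List of `MRDResult` objects.
#' @return Data frame, one row per case (labels dropped).
#' @export
mrd_result_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(case_id = r$case_id, cll_events = r$cll_events,
               wbc_events = r$wbc_events, pct_wbc = r$pct_wbc,
               normalized_count = r$normalized_count, status = r$status,
               deciding_network = r$deciding_network,
               stringsAsFactors = FALSE)
  }))
}
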