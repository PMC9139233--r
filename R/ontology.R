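#' Event-class ontology and the 10-color CLL MRD panel
#'
#' The classifier assigns every event to exactly one of 14 mutually
#' exclusive classes. The order returned here is the canonical ontology
#' order used for network outputs, argmax tie-breaking (lowest index wins)
#' and all tabulations.
#'
#' @return Character vector of the 14 class names.
#' @export
#' @examples
#' cll_classes()
cll_classes <- function() {
  c("CLL_cells", "aggregates", "B_cells", "basophils_dendritic", "blasts",
    "debris", "erythroblasts", "granulocytes", "hematogones", "monocytes",
    "NK_cells", "plasma_cells", "T_cells", "unknown")
}

#' Classes merged into "Other cell categories" for reporting
#'
#' Per-class metric tables report CLL cells, polytypic B cells, hematogones,
#' plasma cells, T cells, aggregates and debris individually; the remaining
#' classes are pooled into a single "Other" category.
#'
#' @return Character vector of class names pooled into Other.
#' @export
other_cell_classes <- function() {
  c("basophils_dendritic", "blasts", "erythroblasts", "granulocytes",
    "monocytes", "NK_cells", "unknown")
}

#' The 13-channel CLL MRD tube
#'
#' Three light-scatter channels (forward scatter area and height, side
#' scatter area) plus ten fluorescence channels. Marker-fluorochrome names
#' follow the single-tube 10-color CLL MRD panel.
#'
#' @return Data frame with columns `name` and `kind`
#'   (`"scatter"` or `"fluorescence"`), 13 rows.
#' @export
#' @examples
#' cll_panel()
cll_panel <- function() {
  data.frame(
    name = c("FSC-A", "FSC-H", "SSC-A",
             "CD5-BV480", "CD19-PE-Cy7", "CD20-APC-H7", "CD22-APC",
             "CD38-APC-R700", "CD43-BV605", "CD45-PerCP-Cy5.5",
             "CD200-BV421", "Kappa-FITC", "Lambda-PE"),
    kind = rep(c("scatter", "fluorescence"), c(3L, 10L)),
    stringsAsFactors = FALSE
  )
}

#' Validate a vector of event labels against the ontology
#'
#' @param labels Character vector (or factor) of per-event labels.
#' @return The labels as a character vector, invisibly usable downstream.
#' @keywords internal
validate_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), cll_classes())
  if (length(bad) > 0L) {
    stop("unknown event class(es): ", paste(bad, collapse = ", "),
         "\nallowed classes: ", paste(cll_classes(), collapse = ", "),
         call. = FALSE)
  }
  labels
}

#' Construct an event matrix
#'
#' An `EventMatrix` is a numeric N x 13 matrix of per-event intensities with
#' the panel channel names as column names. Intensities must be finite.
#'
#' @param values Numeric matrix, one row per event.
#' @param channels Character vector of channel names; defaults to the
#'   CLL MRD panel.
#' @return A numeric matrix of class `EventMatrix`.
#' @export
event_matrix <- function(values, channels = cll_panel()$name) {
  values <- as.matrix(values)
  if (nrow(values) > 0L) storage.mode(values) <- "double"
  if (ncol(values) != length(channels)) {
    stop("event matrix has ", ncol(values), " columns but ",
         length(channels), " channel names", call. = FALSE)
  }
  if (anyDuplicated(channels)) {
    stop("channel names must be unique within a panel", call. = FALSE)
  }
  if (nrow(values) > 0L && !all(is.finite(values))) {
    stop("event intensities must be finite", call. = FALSE)
  }
  colnames(values) <- channels
  class(values) <- c("EventMatrix", class(values))
  values
}

#' Assemble a case sample
#'
#' A `CaseSample` bundles one specimen's events with optional per-event
#' ground-truth labels and case metadata (one analysis tube per case).
#'
#' @param events An `EventMatrix`.
#' @param truth Optional character vector of per-event class labels, same
#'   length as `nrow(events)`.
#' @param case_id Case identifier string.
#' @param specimen `"peripheral_blood"` or `"bone_marrow"`.
#' @param true_cll_fraction Optional simulated CLL fraction of WBC, in
#'   `[0, 1]` (simulation metadata).
#' @return A list of class `CaseSample`.
#' @export
case_sample <- function(events, truth = NULL, case_id = "case",
                        specimen = c("peripheral_blood", "bone_marrow"),
                        true_cll_fraction = NA_real_) {
  specimen <- match.arg(specimen)
  if (!inherits(events, "EventMatrix")) events <- event_matrix(events)
  if (!is.null(truth)) {
    truth <- validate_labels(truth)
    if (length(truth) != nrow(events)) {
      stop("truth labels (", length(truth), ") do not match event count (",
           nrow(events), ")", call. = FALSE)
    }
  }
  structure(
    list(events = events, truth = truth, case_id = as.character(case_id),
         specimen = specimen, true_cll_fraction = true_cll_fraction),
    class = "CaseSample"
  )
}

#' @export
print.CaseSample <- function(x, ...) {
  cat("CaseSample", x$case_id, "(", x$specimen, ")\n")
  cat("  events:", nrow(x$events), "x", ncol(x$events), "\n")
  if (!is.null(x$truth)) {
    n_cll <- sum(x$truth == "CLL_cells")
    cat("  truth labels present; CLL events:", n_cll, "\n")
  } else {
    cat("  no truth labels\n")
  }
  invisible(x)
}
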