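#' Read a Flow Cytometry Standard (FCS) 3.0/3.1 list-mode file
#'
#' Parses the HEADER and primary TEXT segment, then decodes the DATA
#' segment. Supported layouts: list mode (`$MODE L`), data types `F`
#' (32-bit float), `D` (64-bit float) and `I` (16/32-bit unsigned
#' integer), little- or big-endian byte order. Channel names are taken
#' from `$PnS` with `$PnN` as fallback.
#'
#' @param path Path to an FCS file.
#' @param require_panel If `TRUE` (default), error unless the file carries
#'   exactly 13 parameters (the CLL MRD tube); set `FALSE` for generic use.
#' @return An [event_matrix()] with one row per event, in acquisition
#'   order. The parsed keyword list is attached as attribute `"keywords"`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fcs")
#' m <- event_matrix(matrix(runif(26, 1, 100), ncol = 13))
#' write_fcs(m, f)
#' read_fcs(f)
read_fcs <- function(path, require_panel = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  size <- file.info(path)$size
  if (is.na(size) || size < 58) {
    stop("not an FCS file (truncated header): ", path, call. = FALSE)
  }
  raw <- readBin(path, "raw", n = size)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version or malformed header: ",
         deparse(version), call. = FALSE)
  }
  off <- function(i) {
    s <- trimws(rawToChar(raw[(10 + 8 * (i - 1) + 1):(10 + 8 * i)]))
    if (s == "") 0 else suppressWarnings(as.numeric(s))
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)
  if (is.na(text_beg) || is.na(text_end) || text_end <= text_beg ||
      text_end + 1 > size) {
    stop("malformed FCS header: bad TEXT segment offsets", call. = FALSE)
  }
  # FCS offsets are 0-based byte positions, inclusive
  kw <- fcs_parse_text(raw[(text_beg + 1):(text_end + 1)])

  need <- function(key) {
    v <- kw[[key]]
    if (is.null(v)) stop("FCS file missing required keyword ", key,
                         call. = FALSE)
    v
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  mode <- toupper(need("$MODE"))
  if (mode != "L") stop("only list-mode ($MODE L) FCS data is supported",
                        call. = FALSE)
  if (require_panel && n_par != 13L) {
    stop("panel mismatch: expected 13 parameters, file has ", n_par,
         call. = FALSE)
  }
  byteord <- need("$BYTEORD")
  endian <- if (identical(byteord, "1,2,3,4")) "little"
            else if (identical(byteord, "4,3,2,1")) "big"
            else stop("unsupported $BYTEORD: ", byteord, call. = FALSE)
  # FCS 3.x: header offsets of 0 defer to $BEGINDATA/$ENDDATA
  if (is.na(data_beg) || data_beg == 0) data_beg <- as.numeric(need("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0) data_end <- as.numeric(need("$ENDDATA"))

  chan <- vapply(seq_len(n_par), function(i) {
    s <- kw[[sprintf("$P%dS", i)]]
    if (is.null(s) || !nzchar(s)) s <- kw[[sprintf("$P%dN", i)]]
    if (is.null(s)) sprintf("P%d", i) else s
  }, character(1))

  n_values <- n_par * n_tot
  if (n_values == 0L) {
    out <- event_matrix(matrix(numeric(0), ncol = n_par), channels = chan)
    attr(out, "keywords") <- kw
    return(out)
  }
  if (data_end + 1 > size || data_beg < 1 || data_end < data_beg) {
    stop("malformed FCS file: DATA segment outside file", call. = FALSE)
  }
  con <- rawConnection(raw[(data_beg + 1):(data_end + 1)])
  on.exit(close(con))
  values <- switch(dtype,
    F = readBin(con, "numeric", n = n_values, size = 4, endian = endian),
    D = readBin(con, "numeric", n = n_values, size = 8, endian = endian),
    I = {
      bits <- as.integer(kw[["$P1B"]])
      if (!bits %in% c(16L, 32L)) {
        stop("unsupported $PnB for integer data: ", bits, call. = FALSE)
      }
      readBin(con, "integer", n = n_values, size = bits / 8,
              signed = bits > 16L, endian = endian)
    },
    stop("unsupported $DATATYPE: ", dtype, call. = FALSE)
  )
  if (length(values) < n_values) {
    stop("malformed FCS file: DATA segment shorter than $TOT x $PAR",
         call. = FALSE)
  }
  m <- matrix(as.numeric(values), ncol = n_par, byrow = TRUE)
  out <- event_matrix(m, channels = chan)
  attr(out, "keywords") <- kw
  out
}

# Parse a delimited TEXT segment into a named list of keyword values.
# The first byte is the delimiter; a doubled delimiter inside a value is
# an escaped literal delimiter.
fcs_parse_text <- function(bytes) {
  txt <- rawToChar(bytes)
  delim <- substr(txt, 1, 1)
  body <- substr(txt, 2, nchar(txt))
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # merge empty tokens produced by escaped (doubled) delimiters
  tokens <- character(0)
  i <- 1L
  while (i <= length(parts)) {
    tok <- parts[i]
    while (i < length(parts) && parts[i + 1L] == "") {
      # doubled delimiter: append literal delimiter plus following token
      nxt <- if (i + 2L <= length(parts)) parts[i + 2L] else ""
      tok <- paste0(tok, delim, nxt)
      i <- i + 2L
    }
    tokens <- c(tokens, tok)
    i <- i + 1L
  }
  while (length(tokens) > 0L && !nzchar(tokens[length(tokens)])) {
    tokens <- tokens[-length(tokens)]
  }
  if (length(tokens) %% 2 == 1L) tokens <- tokens[-length(tokens)]
  keys <- tokens[seq(1, length(tokens), by = 2)]
  vals <- tokens[seq(2, length(tokens), by = 2)]
  keys <- toupper(trimws(keys))
  out <- as.list(vals)
  names(out) <- keys
  out
}

#' Write an event matrix as an FCS 3.1 file
#'
#' Writes single-dataset, list-mode, 32-bit float data, little-endian.
#' The panel is stored in `$PnN` and `$PnS`; no spillover matrix is
#' written (the pipeline operates on raw, uncompensated intensities).
#'
#' @param events An [event_matrix()] (N x C, any C >= 1).
#' @param path Output file path.
#' @param extra_keywords Optional named character vector of additional
#'   TEXT keywords (e.g. a case identifier).
#' @return Invisibly, `path`.
#' @export
write_fcs <- function(events, path, extra_keywords = NULL) {
  if (!inherits(events, "EventMatrix")) events <- event_matrix(events)
  n <- nrow(events)
  p <- ncol(events)
  chan <- colnames(events)
  delim <- "/"
  esc <- function(x) gsub(delim, paste0(delim, delim), x, fixed = TRUE)

  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n))
  for (i in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), "262144",
            sprintf("$P%dN", i), esc(chan[i]),
            sprintf("$P%dS", i), esc(chan[i]))
  }
  if (!is.null(extra_keywords)) {
    kw <- c(kw, as.vector(rbind(esc(names(extra_keywords)),
                                esc(unname(extra_keywords)))))
  }

  data_bytes <- 4 * n * p
  text_beg <- 58
  # data offsets appear inside TEXT, so iterate until lengths stabilize
  data_beg <- 0; data_end <- 0
  for (iter in 1:5) {
    full <- c(kw, "$BEGINDATA", as.character(data_beg),
              "$ENDDATA", as.character(data_end))
    text <- paste0(delim, paste0(full, delim, collapse = ""))
    text_end <- text_beg + nchar(text, type = "bytes") - 1
    new_beg <- if (n > 0) text_end + 1 else 0
    new_end <- if (n > 0) new_beg + data_bytes - 1 else 0
    if (new_beg == data_beg && new_end == data_end) break
    data_beg <- new_beg; data_end <- new_end
  }

  fmt8 <- function(x) {
    # header fields are 8 ASCII chars; larger offsets go to 0 per FCS 3.1
    if (x > 99999999) "       0" else sprintf("%8d", x)
  }
  header <- paste0("FCS3.1    ",
                   fmt8(text_beg), fmt8(text_end),
                   fmt8(data_beg), fmt8(data_end),
                   fmt8(0), fmt8(0))

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (n > 0) {
    # row-major (event-interleaved) order, float32
    writeBin(as.vector(t(unclass(events))), con, size = 4,
             endian = "little")
  }
  invisible(path)
}

#' Write one FCS file per ground-truth population
#'
#' Splits a labeled case into per-class FCS files (one per non-empty
#' class), mirroring how gated populations are exported for training.
#' Filenames are `<case_id>_<class>.fcs`.
#'
#' @param case A [case_sample()] with truth labels.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written file paths (names are the
#'   classes).
#' @export
write_population_files <- function(case, dir) {
  stopifnot(inherits(case, "CaseSample"))
  if (is.null(case$truth)) {
    stop("case has no truth labels; cannot split by population",
         call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  present <- intersect(cll_classes(), unique(case$truth))
  paths <- character(0)
  for (cls in present) {
    idx <- which(case$truth == cls)
    sub <- event_matrix(unclass(case$events)[idx, , drop = FALSE],
                        channels = colnames(case$events))
    p <- file.path(dir, paste0(case$case_id, "_", cls, ".fcs"))
    write_fcs(sub, p, extra_keywords = c(CASE_ID = case$case_id,
                                         POPULATION = cls))
    paths[cls] <- p
  }
  paths
}

#' Read or write a per-event label sidecar
#'
#' Labels travel beside the FCS file as a two-column CSV
#' (`event_index,label`), order-aligned with the events. Unknown class
#' strings are rejected against the 14-class ontology.
#'
#' @param path Sidecar CSV path.
#' @param n_events Optional event count of the companion FCS file; a
#'   mismatch raises an alignment error.
#' @return `read_labels`: character vector of labels.
#' @export
read_labels <- function(path, n_events = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("event_index", "label") %in% names(df))) {
    stop("label sidecar must have columns event_index,label", call. = FALSE)
  }
  df <- df[order(df$event_index), , drop = FALSE]
  labels <- validate_labels(df$label)
  if (!is.null(n_events) && length(labels) != n_events) {
    stop("label sidecar has ", length(labels), " rows but companion file ",
         "has ", n_events, " events", call. = FALSE)
  }
  labels
}

#' @rdname read_labels
#' @param labels Character vector of per-event class labels.
#' @return `write_labels`: invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  labels <- validate_labels(labels)
  utils::write.csv(
    data.frame(event_index = seq_along(labels), label = labels),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
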