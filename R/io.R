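# Readers and writers for every table and model file the pipeline touches.
# Tables are plain delimited text: tab by default, comma accepted (delimiter
# is sniffed from the first line when not given).

sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a parcellated time-series table
#'
#' Reads a delimited numeric table with frames as rows and regions as
#' columns (optional header row of region names) into a
#' \code{\link{parcellated_scan}}.
#'
#' @param path path to a TSV/CSV file.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id subject identifier to attach.
#' @param scan_kind \code{"task"} or \code{"rest"}.
#' @param sep field separator; sniffed from the first line when \code{NULL}.
#' @return a \code{parcellated_scan}.
#' @export
read_scan <- function(path, tr_seconds, subject_id = basename(path),
                      scan_kind = "task", sep = NULL) {
  sep <- sniff_sep(path, sep)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty scan file: ", path, call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- suppressWarnings(any(is.na(as.numeric(gsub('"', "", fields[[1L]])))))
  if (header) {
    cols <- gsub('^"|"$', "", fields[[1L]])
    fields <- fields[-1L]
  } else cols <- NULL
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged rows in %s: row %d has %d fields, expected %d",
                 path, which(widths != widths[1L])[1L],
                 widths[widths != widths[1L]][1L], widths[1L]), call. = FALSE)
  num <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(num, anyNA, logical(1L)))
  if (length(bad))
    stop(sprintf("non-numeric cell in %s at data row %d", path, bad[1L]),
         call. = FALSE)
  signal <- do.call(rbind, num)
  if (nrow(signal) < 2L)
    stop("scan table must have at least 2 frames", call. = FALSE)
  if (!is.null(cols)) colnames(signal) <- cols
  parcellated_scan(signal, tr_seconds, subject_id = subject_id,
                   scan_kind = scan_kind)
}

#' Write a parcellated scan as a delimited table
#' @param scan a \code{parcellated_scan}.
#' @param path output path.
#' @param sep field separator (tab default).
#' @export
write_scan <- function(scan, path, sep = "\t") {
  utils::write.table(scan$signal, path, sep = sep, row.names = FALSE,
                     col.names = !is.null(colnames(scan$signal)),
                     quote = FALSE)
  invisible(path)
}

#' Read a trial/event table
#'
#' Required columns: \code{trial_index}, \code{center_frame} (0-based frame
#' index of the window center, e.g. the response frame), \code{block_type},
#' \code{response_time_ms}. Missing response times (omitted responses) are
#' preserved as \code{NA}; modeling functions exclude them.
#'
#' @param path path to a TSV/CSV file.
#' @param n_frames optional scan length; when given, centers are checked to
#'   lie in \code{[0, n_frames)}.
#' @param sep field separator; sniffed when \code{NULL}.
#' @return a data.frame with one row per trial.
#' @export
read_events <- function(path, n_frames = NULL, sep = NULL) {
  sep <- sniff_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("trial_index", "center_frame", "block_type", "response_time_ms")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("event table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- if ("subject_id" %in% names(df))
    anyDuplicated(df[c("subject_id", "trial_index")]) else
      anyDuplicated(df$trial_index)
  if (dup)
    stop("duplicate trial_index in event table", call. = FALSE)
  if (any(df$center_frame < 0))
    stop("center_frame must be >= 0", call. = FALSE)
  if (!is.null(n_frames) && any(df$center_frame >= n_frames))
    stop("center_frame beyond scan length", call. = FALSE)
  if (any(!is.na(df$response_time_ms) & df$response_time_ms <= 0))
    stop("response times must be positive (ms)", call. = FALSE)
  df
}

#' Read a subject phenotype table
#'
#' Required columns: \code{subject_id}, \code{trait} (e.g. a fluid
#' intelligence score), \code{mean_fd} (mean frame-to-frame displacement in
#' mm, the standard motion covariate). Extra columns (e.g. per-subject
#' response time targets) are kept.
#'
#' @inheritParams read_events
#' @return a data.frame with one row per subject.
#' @export
read_phenotypes <- function(path, sep = NULL) {
  sep <- sniff_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("subject_id", "trait", "mean_fd")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("phenotype table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in phenotype table", call. = FALSE)
  if (any(df$mean_fd < 0, na.rm = TRUE))
    stop("mean_fd must be non-negative", call. = FALSE)
  df
}

#' Read a region-to-network assignment table
#'
#' Required columns: \code{region_index} (1-based region index) and
#' \code{network_label}; every region must carry exactly one label.
#'
#' @inheritParams read_events
#' @return a data.frame sorted by region index.
#' @export
read_networks <- function(path, sep = NULL) {
  sep <- sniff_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("region_index", "network_label")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("network table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$region_index))
    stop("region labeled more than once: region ",
         df$region_index[duplicated(df$region_index)][1L], call. = FALSE)
  df[order(df$region_index), , drop = FALSE]
}

MODEL_FILE_FORMAT  <- "statecpm-model"
MODEL_FILE_VERSION <- 1L

#' Write / read a fitted model file
#'
#' Models are serialized as versioned, human-readable JSON carrying the edge
#' index convention, the selected-edge mask or selection-frequency vector,
#' linear parameters, window specification, and training provenance (seeds,
#' iteration count, center timepoint). Round-trips are lossless: numeric
#' fields are written at full precision.
#'
#' @param model a \code{cpm_model} or \code{aggregated_model}.
#' @param path output path.
#' @return \code{write_model}: the path, invisibly. \code{read_model}: the
#'   reconstructed model object.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, c("cpm_model", "aggregated_model")))
  fields <- unclass(model)
  if (!is.null(fields$window)) fields$window <- unclass(fields$window)
  payload <- list(
    format = MODEL_FILE_FORMAT,
    version = MODEL_FILE_VERSION,
    model_class = class(model)[1L],
    edge_index_convention = edge_convention(),
    fields = fields)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  if (!identical(payload$format, MODEL_FILE_FORMAT))
    stop("not a statecpm model file: ", path, call. = FALSE)
  if (!identical(as.integer(payload$version), MODEL_FILE_VERSION))
    stop(sprintf("incompatible model file version %s (reader supports %d)",
                 payload$version, MODEL_FILE_VERSION), call. = FALSE)
  if (!identical(payload$edge_index_convention, edge_convention()))
    stop("incompatible edge index convention: ",
         payload$edge_index_convention, call. = FALSE)
  f <- payload$fields
  if (!is.null(f$window) && length(f$window))
    f$window <- structure(f$window, class = "window_spec")
  if (!is.null(f$selected)) f$selected <- as.logical(f$selected)
  cls <- if (identical(payload$model_class, "aggregated_model"))
    c("aggregated_model", "cpm_model") else payload$model_class
  structure(f, class = cls)
}
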