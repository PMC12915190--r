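# Domain containers shared across modules. Plain S3 lists/data.frames with
# validating constructors, in the style of base-R analysis packages.

#' Construct a dual-channel photometry recording
#'
#' A uniformly sampled two-channel fluorescence trace: the sensor-dependent
#' 470 nm channel (\code{f_signal}) and the isosbestic 410 nm control channel
#' (\code{f_control}) used to correct motion artifacts, photobleaching and
#' autofluorescence.
#'
#' @param f_signal numeric vector, 470 nm fluorescence (arbitrary units).
#' @param f_control numeric vector, 410 nm fluorescence (arbitrary units).
#' @param sampling_rate sampling rate in Hz.
#' @param time optional time axis in seconds; defaults to
#'   \code{(0:(n-1))/sampling_rate}. Must be uniformly spaced at
#'   \code{1/sampling_rate} within 1e-6 relative tolerance.
#' @param label free-text label for the recording.
#' @return an object of class \code{photometry_recording}: a list with fields
#'   \code{time}, \code{f_signal}, \code{f_control}, \code{sampling_rate},
#'   \code{label}.
#' @export
photometry_recording <- function(f_signal, f_control, sampling_rate,
                                 time = NULL, label = "") {
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  n <- length(f_signal)
  if (n < 2L || length(f_control) != n) {
    data_error("channels must have equal length >= 2 (got %d and %d)",
               n, length(f_control))
  }
  if (is.null(time)) {
    time <- (seq_len(n) - 1L) / sampling_rate
  } else {
    if (length(time) != n) data_error("'time' length must match channels")
    dt <- diff(time)
    step <- 1 / sampling_rate
    bad <- which(abs(dt - step) > 1e-6 * step)
    if (any(dt <= 0) || length(bad) > 0L) {
      first <- if (length(bad)) bad[1L] + 1L else which(dt <= 0)[1L] + 1L
      format_error("time axis not uniformly increasing at step 1/sampling_rate; first offending row: %d", first)
    }
  }
  structure(list(time = as.numeric(time),
                 f_signal = as.numeric(f_signal),
                 f_control = as.numeric(f_control),
                 sampling_rate = sampling_rate,
                 label = as.character(label)[1L]),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("photometry_recording: %d samples @ %g Hz (%.1f s)%s\n",
              length(x$time), x$sampling_rate,
              length(x$time) / x$sampling_rate,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Construct a behavioral bout annotation
#'
#' Labeled, half-open \code{[onset, offset)} intervals marking struggle and
#' immobility periods of a session (e.g. tail-suspension or forced-swim test).
#'
#' @param onset,offset numeric vectors, interval bounds in seconds.
#' @param label character vector of labels, each \code{"struggle"} or
#'   \code{"immobility"}.
#' @param session_duration total session duration in seconds.
#' @return an object of class \code{bout_annotation}: a data.frame with
#'   columns \code{onset_s}, \code{offset_s}, \code{label} plus attribute
#'   \code{session_duration}.
#' @export
bout_annotation <- function(onset, offset, label, session_duration) {
  check_scalar(session_duration, "session_duration", positive = TRUE)
  n <- length(onset)
  if (length(offset) != n || length(label) != n) {
    data_error("onset, offset and label must have equal length")
  }
  label <- as.character(label)
  bad_lab <- which(!label %in% c("struggle", "immobility"))
  if (length(bad_lab)) {
    data_error("invalid bout label at row %d: '%s'", bad_lab[1L], label[bad_lab[1L]])
  }
  bad <- which(!(onset < offset))
  if (length(bad)) data_error("bout onset >= offset at row %d", bad[1L])
  o <- order(onset)
  onset <- onset[o]; offset <- offset[o]; label <- label[o]
  if (n > 1L && any(onset[-1L] < offset[-n] - 1e-9)) {
    i <- which(onset[-1L] < offset[-n] - 1e-9)[1L]
    data_error("overlapping bouts at rows %d and %d", i, i + 1L)
  }
  if (any(onset < -1e-9) || any(offset > session_duration + 1e-9)) {
    data_error("bouts must lie within [0, session_duration]")
  }
  structure(data.frame(onset_s = onset, offset_s = offset, label = label,
                       stringsAsFactors = FALSE),
            session_duration = session_duration,
            class = c("bout_annotation", "data.frame"))
}

#' Construct a two-group abundance table
#'
#' A features-by-samples matrix of positive normalized abundances with a
#' control/treatment group assignment, the input of the differential-expression
#' screen.
#'
#' @param feature_ids character vector of unique feature identifiers.
#' @param values numeric matrix, features x samples, strictly positive.
#' @param groups character vector (one per sample column) with values
#'   \code{"control"} or \code{"treatment"}; at least 2 samples per group.
#' @return an object of class \code{abundance_table}.
#' @export
abundance_table <- function(feature_ids, values, groups) {
  values <- as.matrix(values)
  if (length(feature_ids) != nrow(values)) {
    data_error("feature_ids length must equal nrow(values)")
  }
  if (anyDuplicated(feature_ids)) data_error("feature ids must be unique")
  if (length(groups) != ncol(values)) {
    data_error("groups length must equal ncol(values)")
  }
  groups <- as.character(groups)
  if (!all(groups %in% c("control", "treatment"))) {
    data_error("groups must be 'control' or 'treatment'")
  }
  if (sum(groups == "control") < 2L || sum(groups == "treatment") < 2L) {
    data_error("need >= 2 samples per group")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    data_error("abundances must be finite and > 0")
  }
  rownames(values) <- feature_ids
  structure(list(feature_ids = as.character(feature_ids),
                 values = values, groups = groups),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d features x %d samples (%d control, %d treatment)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "control"), sum(x$groups == "treatment")))
  invisible(x)
}

#' Construct a gene set
#'
#' @param name set name (e.g. pathway or database label).
#' @param ids character vector of member identifiers; normalized with
#'   \code{\link{normalize_ids}} and deduplicated.
#' @param source free-text provenance (e.g. \code{"FerrDB"}).
#' @return an object of class \code{gene_set}.
#' @export
gene_set <- function(name, ids, source = "") {
  ids <- unique(normalize_ids(ids))
  if (length(ids) == 0L) data_error("gene set '%s' has no ids", name)
  structure(list(name = as.character(name)[1L], ids = ids,
                 source = as.character(source)[1L]),
            class = "gene_set")
}

#' Construct a simple undirected interaction network
#'
#' Edges are stored as unique unordered pairs; self-loops are forbidden.
#'
#' @param from,to character vectors of node identifiers (one edge per element).
#' @param nodes optional character vector of all node ids, to retain
#'   zero-degree nodes; defaults to the ids appearing in edges.
#' @return an object of class \code{interaction_network}: list with
#'   \code{nodes} and an edge data.frame (\code{from < to} lexicographically).
#' @export
interaction_network <- function(from, to, nodes = NULL) {
  from <- as.character(from); to <- as.character(to)
  if (length(from) != length(to)) data_error("'from' and 'to' must have equal length")
  if (any(from == to)) data_error("self-loop edges are not allowed")
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate edge(s)", sum(dup)))
    a <- a[!dup]; b <- b[!dup]
  }
  if (is.null(nodes)) nodes <- sort(unique(c(a, b))) else nodes <- sort(unique(as.character(nodes)))
  missing_nodes <- setdiff(unique(c(a, b)), nodes)
  if (length(missing_nodes)) data_error("edge endpoint(s) not in node list: %s",
                                        paste(utils::head(missing_nodes, 3L), collapse = ", "))
  o <- order(a, b)
  structure(list(nodes = nodes,
                 edges = data.frame(from = a[o], to = b[o], stringsAsFactors = FALSE)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
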