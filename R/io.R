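# File-format readers and writers. Dialects are pinned, not sniffed: UTF-8,
# LF, '.' decimal separator, no quoting. Times in seconds, half-open
# [onset, offset) intervals.

#' Read a photometry recording from CSV
#'
#' Expects header \code{time_s,f470,f410} and a numeric body with a uniformly
#' increasing time axis (step tolerance 1e-6 relative).
#'
#' @param path file path.
#' @return a \code{\link{photometry_recording}}.
#' @export
read_photometry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "f470", "f410")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    format_error("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", "))
  }
  for (cn in need) {
    if (!is.numeric(df[[cn]])) format_error("non-numeric values in column '%s'", cn)
  }
  if (nrow(df) < 2L) format_error("need >= 2 rows in %s", path)
  dt <- diff(df$time_s)
  step <- stats::median(dt)
  bad <- which(dt <= 0 | abs(dt - step) > 1e-6 * step)
  if (length(bad)) {
    format_error("non-uniform time axis in %s; first offending data row: %d",
                 path, bad[1L] + 1L)
  }
  photometry_recording(df$f470, df$f410, sampling_rate = 1 / step,
                       time = df$time_s, label = basename(path))
}

#' Write a photometry recording to CSV
#'
#' @param rec a \code{\link{photometry_recording}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_photometry_csv <- function(rec, path) {
  stopifnot(inherits(rec, "photometry_recording"))
  df <- data.frame(time_s = rec$time, f470 = rec$f_signal, f410 = rec$f_control)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read behavioral bouts from TSV
#'
#' Expects columns \code{onset_s}, \code{offset_s}, \code{label}.
#'
#' @param path file path.
#' @param session_duration total session length in seconds; defaults to the
#'   largest offset.
#' @return a \code{\link{bout_annotation}}.
#' @export
read_bouts_tsv <- function(path, session_duration = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "offset_s", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    format_error("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(df$onset_s < df$offset_s))
  if (length(bad)) {
    format_error("onset_s >= offset_s in %s at line %d", path, bad[1L] + 1L)
  }
  if (is.null(session_duration)) session_duration <- max(df$offset_s)
  bout_annotation(df$onset_s, df$offset_s, df$label, session_duration)
}

#' Write behavioral bouts to TSV
#' @param bouts a \code{\link{bout_annotation}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bouts_tsv <- function(bouts, path) {
  stopifnot(inherits(bouts, "bout_annotation"))
  utils::write.table(as.data.frame(bouts), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: \code{name<TAB>source<TAB>id1<TAB>id2...}. Duplicate ids within
#' a set are deduplicated with a warning.
#'
#' @param path file path.
#' @return list of \code{\link{gene_set}} objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      format_error("GMT line %d needs name, source and >= 1 id", i)
    }
    ids <- parts[-(1:2)]
    ndup <- sum(duplicated(normalize_ids(ids)))
    if (ndup > 0L) warning(sprintf("GMT line %d: %d duplicate id(s) removed", i, ndup))
    gene_set(parts[1L], ids, source = parts[2L])
  })
}

#' Write gene sets to a GMT file
#' @param sets list of \code{\link{gene_set}} objects (or a single one).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$source)) s$source else ".", s$ids),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an abundance table plus its sample-group map
#'
#' The table TSV has \code{feature_id} as its first column and one column per
#' sample; the groups TSV has two columns, \code{sample} and \code{group}
#' (values \code{control}/\code{treatment}). Duplicate feature ids are
#' deduplicated (first kept) with a warning; non-positive abundances are a
#' validation error naming the line.
#'
#' @param table_path,groups_path file paths.
#' @return an \code{\link{abundance_table}}.
#' @export
read_table_tsv <- function(table_path, groups_path) {
  df <- utils::read.delim(table_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1L] != "feature_id") {
    format_error("first column of %s must be 'feature_id'", table_path)
  }
  gr <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(gr))) {
    format_error("%s needs columns 'sample' and 'group'", groups_path)
  }
  dup <- duplicated(df$feature_id)
  if (any(dup)) {
    warning(sprintf("%d duplicate feature id(s) dropped (first kept)", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) format_error("non-numeric abundances in %s", table_path)
  bad <- which(apply(mat, 1L, function(r) any(!is.finite(r) | r <= 0)))
  if (length(bad)) {
    format_error("non-positive abundance in %s at line %d", table_path,
                 bad[1L] + 1L)
  }
  samples <- colnames(mat)
  missing_samples <- setdiff(samples, gr$sample)
  if (length(missing_samples)) {
    format_error("sample(s) missing from group map: %s",
                 paste(missing_samples, collapse = ", "))
  }
  groups <- gr$group[match(samples, gr$sample)]
  abundance_table(df$feature_id, mat, groups)
}

#' Write an abundance table and its group map
#' @param table an \code{\link{abundance_table}}.
#' @param table_path,groups_path output paths.
#' @return \code{table_path}, invisibly.
#' @export
write_table_tsv <- function(table, table_path, groups_path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(feature_id = table$feature_ids,
                   table$values, check.names = FALSE)
  utils::write.table(df, table_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(sample = colnames(table$values),
                                group = table$groups),
                     groups_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(table_path)
}

#' Read an undirected edge list from TSV
#'
#' First two columns are the edge endpoints. Self-loops are a validation error
#' naming the line; duplicate (unordered) edges are deduplicated with a
#' warning.
#'
#' @param path file path.
#' @return an \code{\link{interaction_network}}.
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) format_error("%s needs two id columns", path)
  from <- as.character(df[[1L]]); to <- as.character(df[[2L]])
  loops <- which(from == to)
  if (length(loops)) {
    format_error("self-loop edge in %s at line %d", path, loops[1L] + 1L)
  }
  interaction_network(from, to)
}

#' Write an edge list to TSV
#' @param network an \code{\link{interaction_network}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edges_tsv <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  utils::write.table(network$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write detected events to TSV
#' @param events a \code{\link{detect_events}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a peri-event matrix to CSV
#'
#' First column \code{relative_time_s}, then one column per trial.
#' @param m a \code{\link{extract_peri_event}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_peri_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "peri_event_matrix"))
  df <- data.frame(relative_time_s = m$relative_time, t(m$values))
  names(df)[-1L] <- sprintf("trial_%d", seq_len(nrow(m$values)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write any summary object to JSON
#' @param x a list-like summary (e.g. \code{event_summary},
#'   \code{screen_summary}, \code{enrichment_result}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
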