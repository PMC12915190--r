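# Peri-event analysis: extract signal windows aligned to behavioral bout
# onsets and average them.

#' Extract peri-event windows aligned to bout onsets
#'
#' One row per qualifying bout onset of the requested label. A window covers
#' \code{[-window_pre, +window_post]} seconds around the onset
#' (\code{round((pre+post)*sampling_rate) + 1} samples); onsets whose window
#' would extend past either end of the recording are dropped and counted in
#' \code{n_dropped}.
#'
#' @param z a \code{\link{zscore_trace}} result (or a \code{corrected_trace};
#'   any object with \code{z} or \code{dff}, \code{time}, \code{sampling_rate}).
#' @param bouts a \code{\link{bout_annotation}}.
#' @param label bout label to align to (default \code{"struggle"}).
#' @param window_pre,window_post window extent in seconds before/after onset.
#' @return an object of class \code{peri_event_matrix}: list with
#'   \code{values} (trials x timepoints), \code{relative_time} (s, 0 = onset),
#'   \code{align_times}, \code{window_pre}, \code{window_post},
#'   \code{n_dropped}.
#' @export
extract_peri_event <- function(z, bouts, label = "struggle",
                               window_pre = 2, window_post = 6) {
  stopifnot(inherits(bouts, "bout_annotation"))
  check_scalar(window_pre, "window_pre", nonneg = TRUE)
  check_scalar(window_post, "window_post", positive = TRUE)
  y <- if (!is.null(z$z)) z$z else z$dff
  if (is.null(y)) param_error("'z' must be a z-scored or corrected trace")
  fs <- z$sampling_rate
  time <- z$time
  n <- length(y)
  onsets <- bouts$onset_s[bouts$label == label]
  if (length(onsets) == 0L) {
    data_error("no bouts with label '%s'", label)
  }
  n_pre <- round(window_pre * fs)
  n_post <- round(window_post * fs)
  i0 <- round((onsets - time[1L]) * fs) + 1L
  ok <- (i0 - n_pre) >= 1L & (i0 + n_post) <= n
  n_dropped <- sum(!ok)
  if (!any(ok)) {
    data_error("no qualifying bouts: all %d onset window(s) exceed the recording",
               n_dropped)
  }
  rows <- t(vapply(i0[ok], function(i) y[(i - n_pre):(i + n_post)],
                   numeric(n_pre + n_post + 1L)))
  structure(list(values = rows,
                 relative_time = (seq_len(n_pre + n_post + 1L) - 1L - n_pre) / fs,
                 align_times = onsets[ok],
                 window_pre = window_pre, window_post = window_post,
                 n_dropped = n_dropped),
            class = "peri_event_matrix")
}

#' @export
print.peri_event_matrix <- function(x, ...) {
  cat(sprintf("peri_event_matrix: %d trial(s) x %d timepoints, window [-%g, +%g] s (%d dropped)\n",
              nrow(x$values), ncol(x$values), x$window_pre, x$window_post,
              x$n_dropped))
  invisible(x)
}

#' Average peri-event z over a sub-window
#'
#' Per-trial mean of samples with relative time in \code{[from_t, to_t]}
#' (inclusive), and the grand mean across trials — the standard quantification
#' of average signal intensity within a fixed window after event onset.
#'
#' @param m a \code{\link{extract_peri_event}} result.
#' @param from_t,to_t sub-window bounds in seconds relative to onset; must lie
#'   within \code{[-window_pre, window_post]}.
#' @return list with \code{per_trial} (one mean per trial) and
#'   \code{grand_mean}.
#' @export
mean_peri_event_z <- function(m, from_t = 0, to_t = 6) {
  stopifnot(inherits(m, "peri_event_matrix"))
  if (from_t < -m$window_pre - 1e-9 || to_t > m$window_post + 1e-9 ||
      from_t > to_t) {
    param_error("[from_t, to_t] must be an ordered sub-window of [-%g, %g]",
                m$window_pre, m$window_post)
  }
  sel <- m$relative_time >= from_t - 1e-9 & m$relative_time <= to_t + 1e-9
  if (!any(sel)) param_error("empty sub-window: no samples in [%g, %g]", from_t, to_t)
  per_trial <- rowMeans(m$values[, sel, drop = FALSE])
  list(per_trial = per_trial, grand_mean = mean(per_trial))
}
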