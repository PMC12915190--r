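# Threshold-based transient detection and per-event metrics: peak amplitude,
# AUC above baseline, single-exponential decay tau.

#' Event-detection parameters
#'
#' The detection threshold is \code{baseline mean + k_sd * baseline SD} of the
#' dF/F trace; a detected run must additionally peak at or above
#' \code{amplitude_floor}. The floor default of 0.02 reads the conventional
#' "dF/F >= 2" criterion in percent units (a dF/F ratio of 2, i.e. 200%, is
#' implausible for these sensors); pass a different floor for other readings.
#'
#' @param k_sd baseline-SD multiplier (default 3).
#' @param amplitude_floor minimum peak dF/F (ratio units; default 0.02 = 2%).
#' @param min_separation events closer than this (s) are merged (default 0.5).
#' @param baseline_mode \code{"whole_trace"}: baseline mean/SD from the whole
#'   trace; \code{"iterative_exclusion"}: re-estimated twice after excluding
#'   super-threshold samples.
#' @return a validated list of class \code{event_detection_params}.
#' @export
event_detection_params <- function(k_sd = 3, amplitude_floor = 0.02,
                                   min_separation = 0.5,
                                   baseline_mode = c("whole_trace",
                                                     "iterative_exclusion")) {
  check_scalar(k_sd, "k_sd", positive = TRUE)
  check_scalar(amplitude_floor, "amplitude_floor", nonneg = TRUE)
  check_scalar(min_separation, "min_separation", nonneg = TRUE)
  baseline_mode <- match.arg(baseline_mode)
  structure(list(k_sd = k_sd, amplitude_floor = amplitude_floor,
                 min_separation = min_separation,
                 baseline_mode = baseline_mode),
            class = "event_detection_params")
}

baseline_stats <- function(dff, params) {
  m <- mean(dff); s <- sd_pop(dff)
  if (params$baseline_mode == "whole_trace") {
    if (s == 0) data_error("degenerate baseline: whole-trace SD is zero")
    return(list(mean = m, sd = s))
  }
  # iterative_exclusion: 2 passes removing super-threshold samples; a tiny SD
  # guard keeps a constant trace from erroring (it then yields zero events)
  for (i in 1:2) {
    thr <- m + params$k_sd * max(s, .Machine$double.eps)
    keep <- dff <= thr
    if (!any(keep)) break
    m <- mean(dff[keep]); s <- sd_pop(dff[keep])
  }
  list(mean = m, sd = max(s, .Machine$double.eps))
}

#' Detect transient events by baseline thresholding
#'
#' An event is a maximal run of samples with \code{dff > T}, where
#' \code{T = baseline_mean + k_sd * baseline_SD}. Runs separated by less than
#' \code{min_separation} seconds are merged, then runs whose peak falls below
#' \code{amplitude_floor} are discarded. Per event: onset = first sample above
#' \code{T}; end = first return below \code{T} (or trace end); AUC = trapezoidal
#' integral of \code{dff - baseline_mean} over \code{[onset, end]}, floored at
#' 0; decay tau from a bounded single-exponential fit of the peak-to-end
#' segment (\code{NA} if the segment has fewer than 5 samples or the fit
#' fails — the event is retained either way).
#'
#' @param trace a \code{\link{compute_dff}} result.
#' @param params an \code{\link{event_detection_params}} object.
#' @return a data.frame of class \code{transient_events} with columns
#'   \code{onset_t}, \code{peak_t}, \code{end_t}, \code{peak_amp} (dF/F),
#'   \code{peak_amp_pct} (100 * dF/F), \code{auc}, \code{tau_s}, \code{r2};
#'   attributes \code{baseline_mean}, \code{baseline_sd}, \code{threshold},
#'   \code{session_duration}.
#' @export
detect_events <- function(trace, params = event_detection_params()) {
  stopifnot(inherits(trace, "corrected_trace"))
  if (!inherits(params, "event_detection_params")) {
    params <- do.call(event_detection_params, as.list(params))
  }
  dff <- trace$dff
  if (any(!is.finite(dff))) data_error("non-finite values in dF/F trace")
  fs <- trace$sampling_rate
  bl <- baseline_stats(dff, params)
  thr <- bl$mean + params$k_sd * bl$sd
  above <- dff > thr
  empty <- data.frame(onset_t = numeric(0), peak_t = numeric(0),
                      end_t = numeric(0), peak_amp = numeric(0),
                      peak_amp_pct = numeric(0), auc = numeric(0),
                      tau_s = numeric(0), r2 = numeric(0))
  session_duration <- length(dff) / fs
  decorate <- function(df) {
    structure(df, baseline_mean = bl$mean, baseline_sd = bl$sd,
              threshold = thr, session_duration = session_duration,
              class = c("transient_events", "data.frame"))
  }
  if (!any(above)) return(decorate(empty))
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  run_start <- starts_idx[r$values]
  run_stop <- ends_idx[r$values]               # last sample above threshold
  n <- length(dff)
  run_end <- pmin(run_stop + 1L, n)            # first return below T (or end)
  # merge runs separated by < min_separation seconds
  if (length(run_start) > 1L && params$min_separation > 0) {
    gap_s <- (run_start[-1L] - run_end[-length(run_end)]) / fs
    grp <- cumsum(c(1L, as.integer(gap_s >= params$min_separation)))
    run_start <- tapply(run_start, grp, min)
    run_end <- tapply(run_end, grp, max)
  }
  t0 <- trace$time[1L]
  out <- lapply(seq_along(run_start), function(i) {
    s <- run_start[i]; e <- run_end[i]
    seg <- dff[s:e]
    pk_rel <- which.max(seg)
    pk <- s + pk_rel - 1L
    peak_amp <- dff[pk]
    if (peak_amp < params$amplitude_floor) return(NULL)
    auc <- max(0, trapz_uniform(dff[s:e] - bl$mean, 1 / fs))
    decay <- dff[pk:e]
    ft <- if (length(decay) >= 5L) fit_decay_tau(decay, fs) else
      list(tau = NA_real_, r2 = NA_real_)
    data.frame(onset_t = t0 + (s - 1L) / fs, peak_t = t0 + (pk - 1L) / fs,
               end_t = t0 + (e - 1L) / fs, peak_amp = peak_amp,
               peak_amp_pct = 100 * peak_amp, auc = auc,
               tau_s = ft$tau, r2 = ft$r2)
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) return(decorate(empty))
  decorate(do.call(rbind, out))
}

#' Fit a single-exponential decay time constant
#'
#' Least-squares fit of \code{y(t) = A * exp(-t/tau) + C} to a decay segment
#' starting at the event peak (t = 0 at the first sample). tau is initialized
#' from the time-to-half-peak divided by ln 2, A from the peak height and C
#' from the segment tail; positivity of tau is enforced by optimizing over
#' log(tau). Fit failure returns \code{tau = NA} rather than an error.
#'
#' @param y numeric vector, dF/F decay segment starting at the peak.
#' @param sampling_rate Hz.
#' @return list with \code{tau} (s, \code{NA} on failure) and \code{r2}.
#' @export
fit_decay_tau <- function(y, sampling_rate) {
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  m <- length(y)
  if (m < 5L) return(list(tau = NA_real_, r2 = NA_real_))
  s <- (seq_len(m) - 1L) / sampling_rate
  tail_n <- max(3L, m %/% 10L)
  C0 <- mean(y[(m - tail_n + 1L):m])
  A0 <- y[1L] - C0
  sst <- sum((y - mean(y))^2)
  if (A0 <= 0 || sst == 0) return(list(tau = NA_real_, r2 = NA_real_))
  half <- C0 + A0 / 2
  ih <- which(y <= half)[1L]
  tau0 <- if (!is.na(ih) && ih > 1L) s[ih] / log(2) else s[m] / 3
  tau0 <- max(tau0, 1 / sampling_rate)
  obj <- function(par) {
    pred <- par[1L] * exp(-s / exp(par[2L])) + par[3L]
    sum((y - pred)^2)
  }
  fit <- tryCatch(
    stats::optim(c(A0, log(tau0), C0), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(tau = NA_real_, r2 = NA_real_))
  tau <- exp(fit$par[2L])
  r2 <- 1 - fit$value / sst
  if (!is.finite(tau) || tau <= 0) return(list(tau = NA_real_, r2 = NA_real_))
  list(tau = tau, r2 = r2)
}

#' Summarize detected events for a session
#'
#' @param events a \code{\link{detect_events}} result (or compatible
#'   data.frame with \code{auc} and \code{tau_s} columns).
#' @param session_duration session length in seconds; defaults to the
#'   attribute stored by \code{detect_events}.
#' @return an object of class \code{event_summary}: list with
#'   \code{n_events}, \code{frequency} (events/min), \code{mean_auc},
#'   \code{mean_tau} (means over events with valid values; \code{NA} when no
#'   events), \code{session_minutes}.
#' @export
summarize_events <- function(events, session_duration = NULL) {
  if (is.null(session_duration)) {
    session_duration <- attr(events, "session_duration")
  }
  check_scalar(session_duration, "session_duration", positive = TRUE)
  n <- nrow(events)
  mins <- session_duration / 60
  structure(list(
    n_events = n,
    frequency = n / mins,
    mean_auc = if (n > 0L) mean(events$auc, na.rm = TRUE) else NA_real_,
    mean_tau = if (n > 0L && any(!is.na(events$tau_s)))
      mean(events$tau_s, na.rm = TRUE) else NA_real_,
    session_minutes = mins), class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("event_summary: %d events in %.2f min (%.3f events/min); mean AUC %.4g, mean tau %.3g s\n",
              x$n_events, x$session_minutes, x$frequency,
              x$mean_auc, x$mean_tau))
  invisible(x)
}
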