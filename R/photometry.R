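# Isosbestic correction pipeline: fit the 410 nm control channel to the 470 nm
# signal channel, form dF/F against the fitted control, z-score.

#' Fit the isosbestic control channel to the signal channel
#'
#' Least-squares fit of the 470 nm signal on the 410 nm control:
#' \code{fitted = a + b * f_control}, where \code{(a, b)} minimize
#' \code{sum((f_signal - a - b*f_control)^2)}. The fitted control is the
#' motion/bleaching reference used by \code{\link{compute_dff}}.
#'
#' @param rec a \code{\link{photometry_recording}}.
#' @param method \code{"ols"} (default, tested) or \code{"robust"}
#'   (Huber M-estimate via \code{MASS::rlm}, if MASS is installed).
#' @return an object of class \code{control_fit}: list with \code{a}
#'   (intercept), \code{b} (slope), \code{fitted} series and
#'   \code{residual_rms}.
#' @export
fit_control_channel <- function(rec, method = c("ols", "robust")) {
  stopifnot(inherits(rec, "photometry_recording"))
  method <- match.arg(method)
  if (anyNA(rec$f_signal) || anyNA(rec$f_control) ||
      any(!is.finite(rec$f_signal)) || any(!is.finite(rec$f_control))) {
    data_error("NaN/Inf in signal or control channel")
  }
  if (sd_pop(rec$f_control) == 0) {
    data_error("control channel is constant: degenerate fit")
  }
  if (method == "ols") {
    b <- stats::cov(rec$f_signal, rec$f_control) / stats::var(rec$f_control)
    a <- mean(rec$f_signal) - b * mean(rec$f_control)
  } else {
    if (!requireNamespace("MASS", quietly = TRUE)) {
      param_error("method='robust' requires the MASS package")
    }
    fit <- MASS::rlm(rec$f_signal ~ rec$f_control, maxit = 50)
    a <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
  }
  fitted <- a + b * rec$f_control
  structure(list(a = a, b = b, fitted = fitted,
                 residual_rms = sqrt(mean((rec$f_signal - fitted)^2)),
                 method = method),
            class = "control_fit")
}

#' Compute dF/F against the fitted control channel
#'
#' \code{dff[i] = (f_signal[i] - fitted[i]) / fitted[i]}: the fractional
#' fluorescence change of the signal channel relative to the fitted isosbestic
#' reference, which cancels shared motion artifacts and bleaching.
#'
#' @param rec a \code{\link{photometry_recording}}.
#' @param fit a \code{\link{fit_control_channel}} result; computed if omitted.
#' @return an object of class \code{corrected_trace}: list with \code{dff}
#'   (dimensionless), \code{time} (s) and \code{sampling_rate} (Hz).
#' @export
compute_dff <- function(rec, fit = NULL) {
  stopifnot(inherits(rec, "photometry_recording"))
  if (is.null(fit)) fit <- fit_control_channel(rec)
  stopifnot(inherits(fit, "control_fit"))
  if (length(fit$fitted) != length(rec$f_signal)) {
    data_error("fit length does not match recording")
  }
  bad <- which(fit$fitted <= 0)
  if (length(bad)) {
    data_error("fitted control <= 0 at %d sample(s); first indices: %s",
               length(bad), paste(utils::head(bad, 5L), collapse = ", "))
  }
  dff <- (rec$f_signal - fit$fitted) / fit$fitted
  structure(list(dff = dff, time = rec$time,
                 sampling_rate = rec$sampling_rate),
            class = "corrected_trace")
}

#' Z-score a corrected trace
#'
#' \code{z = (dff - mean) / sd} using the whole-trace arithmetic mean and the
#' population (denominator-N) standard deviation. The output has mean 0 and
#' SD 1 by construction.
#'
#' @param trace a \code{\link{compute_dff}} result.
#' @return an object of class \code{zscored_trace}: list with \code{z},
#'   \code{mean_used}, \code{sd_used}, \code{time}, \code{sampling_rate}.
#' @export
zscore_trace <- function(trace) {
  stopifnot(inherits(trace, "corrected_trace"))
  if (length(trace$dff) < 2L) data_error("trace must have >= 2 samples")
  m <- mean(trace$dff)
  s <- sd_pop(trace$dff)
  if (s == 0) data_error("constant trace: zero SD, cannot z-score")
  structure(list(z = (trace$dff - m) / s, mean_used = m, sd_used = s,
                 time = trace$time, sampling_rate = trace$sampling_rate),
            class = "zscored_trace")
}
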