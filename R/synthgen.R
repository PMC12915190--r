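# Seeded synthetic-data generators with known ground truth. Every generator is
# a pure function of (params, seed): RNG state is saved/restored around each
# call and never leaks.

#' Parameters for the photometry simulator
#'
#' Defaults describe a 10-minute session at 20 Hz with transients at 6
#' events/min, amplitude ~5% dF/F decaying with tau = 1 s, slow exponential
#' photobleaching in both channels, a shared slow motion artifact, and 1%
#' (of baseline) Gaussian channel noise. The sampling rate and noise level are
#' package choices (the class of recordings emulated does not pin them down);
#' see the methods vignette.
#'
#' @param duration session length, seconds.
#' @param sampling_rate Hz.
#' @param event_rate transient rate, events/min (Poisson process intensity).
#' @param amplitude_mean,amplitude_sd transient peak amplitude in dF/F units
#'   (Gaussian, truncated at 0).
#' @param decay_tau transient decay time constant, seconds.
#' @param rise_time linear rise time, seconds (0 = instantaneous rise).
#' @param bleach_tau_signal,bleach_tau_control exponential photobleaching time
#'   constants, seconds (\code{Inf} = no bleaching).
#' @param artifact_sd standard deviation of the shared multiplicative motion
#'   artifact (relative amplitude; 0 disables it).
#' @param artifact_cutoff_hz low-pass cutoff of the artifact process, Hz.
#' @param noise_sd per-channel additive Gaussian noise SD, fluorescence a.u.
#' @param baseline_f baseline fluorescence, a.u.
#' @param seed integer RNG seed.
#' @return a validated list of class \code{photometry_sim_params}.
#' @export
photometry_sim_params <- function(duration = 600, sampling_rate = 20,
                                  event_rate = 6, amplitude_mean = 0.05,
                                  amplitude_sd = 0.01, decay_tau = 1,
                                  rise_time = 0.1,
                                  bleach_tau_signal = 1500,
                                  bleach_tau_control = 1500,
                                  artifact_sd = 0.02,
                                  artifact_cutoff_hz = 0.1,
                                  noise_sd = 1, baseline_f = 100,
                                  seed = 1L) {
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar(event_rate, "event_rate", nonneg = TRUE)
  check_scalar(amplitude_mean, "amplitude_mean", nonneg = TRUE)
  check_scalar(amplitude_sd, "amplitude_sd", nonneg = TRUE)
  check_scalar(decay_tau, "decay_tau", positive = TRUE)
  check_scalar(rise_time, "rise_time", nonneg = TRUE)
  check_scalar(bleach_tau_signal, "bleach_tau_signal", positive = TRUE, finite = FALSE)
  check_scalar(bleach_tau_control, "bleach_tau_control", positive = TRUE, finite = FALSE)
  check_scalar(artifact_sd, "artifact_sd", nonneg = TRUE)
  check_scalar(artifact_cutoff_hz, "artifact_cutoff_hz", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(baseline_f, "baseline_f", positive = TRUE)
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 event_rate = event_rate, amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd, decay_tau = decay_tau,
                 rise_time = rise_time,
                 bleach_tau_signal = bleach_tau_signal,
                 bleach_tau_control = bleach_tau_control,
                 artifact_sd = artifact_sd,
                 artifact_cutoff_hz = artifact_cutoff_hz,
                 noise_sd = noise_sd, baseline_f = baseline_f,
                 seed = as.integer(seed)),
            class = "photometry_sim_params")
}

# Shared slow artifact: Gaussian random walk passed through a single-pole
# low-pass filter at `cutoff_hz`, rescaled to the requested SD. Identical in
# both channels before channel noise (the premise of isosbestic correction).
simulate_artifact <- function(n, sampling_rate, sd_target, cutoff_hz) {
  if (sd_target == 0 || n < 2L) return(numeric(n))
  walk <- cumsum(stats::rnorm(n))
  dt <- 1 / sampling_rate
  rc <- 1 / (2 * pi * cutoff_hz)
  alpha <- dt / (rc + dt)
  sm <- as.numeric(stats::filter(alpha * walk, 1 - alpha,
                                 method = "recursive", init = walk[1L]))
  sm <- sm - mean(sm)
  s <- sd_pop(sm)
  if (s == 0) return(numeric(n))
  sm / s * sd_target
}

# Transient kernel: linear rise over rise_time to `amp`, then single
# exponential decay with time constant `tau`. Overlapping transients sum.
transient_sum <- function(t, onsets, amps, tau, rise_time) {
  out <- numeric(length(t))
  for (i in seq_along(onsets)) {
    dtx <- t - onsets[i]
    active <- dtx >= 0
    if (!any(active)) next
    d <- dtx[active]
    if (rise_time > 0) {
      y <- ifelse(d < rise_time, amps[i] * d / rise_time,
                  amps[i] * exp(-(d - rise_time) / tau))
    } else {
      y <- amps[i] * exp(-d / tau)
    }
    out[active] <- out[active] + y
  }
  out
}

#' Simulate a dual-channel photometry recording with known ground truth
#'
#' Control channel: \code{baseline_f * bleach_c(t) * (1 + artifact(t)) + noise}.
#' Signal channel: \code{baseline_f * bleach_s(t) * (1 + artifact(t)) *
#' (1 + sum of transients(t)) + noise}. The artifact term is a shared
#' low-pass-filtered Gaussian walk, identical in both channels before
#' channel-specific noise. Transient onsets follow a homogeneous Poisson
#' process at \code{event_rate}; each transient rises linearly over
#' \code{rise_time} then decays as \code{amp * exp(-t/decay_tau)}; overlapping
#' transients sum additively.
#'
#' @param params a \code{\link{photometry_sim_params}} object.
#' @return list with elements \code{recording}
#'   (\code{\link{photometry_recording}}) and \code{events}: a data.frame of
#'   ground truth (\code{onset_s}, \code{amplitude}) plus attribute
#'   \code{decay_tau}.
#' @export
#' @examples
#' sim <- simulate_photometry(photometry_sim_params(duration = 60, seed = 7))
#' sim$recording
#' nrow(sim$events)
simulate_photometry <- function(params) {
  if (!inherits(params, "photometry_sim_params")) {
    params <- do.call(photometry_sim_params, as.list(params))
  }
  p <- params
  n <- round(p$duration * p$sampling_rate)
  t <- (seq_len(n) - 1L) / p$sampling_rate
  res <- with_seed(p$seed, {
    n_ev <- stats::rpois(1L, p$event_rate / 60 * p$duration)
    onsets <- sort(stats::runif(n_ev, 0, p$duration))
    amps <- pmax(stats::rnorm(n_ev, p$amplitude_mean, p$amplitude_sd), 0)
    artifact <- simulate_artifact(n, p$sampling_rate, p$artifact_sd,
                                  p$artifact_cutoff_hz)
    noise_s <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else numeric(n)
    noise_c <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else numeric(n)
    list(onsets = onsets, amps = amps, artifact = artifact,
         noise_s = noise_s, noise_c = noise_c)
  })
  bleach_s <- if (is.finite(p$bleach_tau_signal)) exp(-t / p$bleach_tau_signal) else rep(1, n)
  bleach_c <- if (is.finite(p$bleach_tau_control)) exp(-t / p$bleach_tau_control) else rep(1, n)
  trans <- transient_sum(t, res$onsets, res$amps, p$decay_tau, p$rise_time)
  f_control <- p$baseline_f * bleach_c * (1 + res$artifact) + res$noise_c
  f_signal <- p$baseline_f * bleach_s * (1 + res$artifact) * (1 + trans) + res$noise_s
  rec <- photometry_recording(f_signal, f_control, p$sampling_rate,
                              label = sprintf("sim seed=%d", p$seed))
  events <- data.frame(onset_s = res$onsets, amplitude = res$amps)
  attr(events, "decay_tau") <- p$decay_tau
  list(recording = rec, events = events)
}

#' Simulate alternating struggle/immobility bouts
#'
#' Bout lengths are exponentially distributed with the stated means; labels
#' alternate starting with \code{start_label}; the intervals tile
#' \code{[0, duration)} exactly (the last bout is truncated).
#'
#' @param duration session length, seconds.
#' @param mean_struggle,mean_immobile mean bout lengths, seconds.
#' @param seed integer RNG seed.
#' @param start_label first bout label.
#' @return a \code{\link{bout_annotation}}.
#' @export
simulate_bouts <- function(duration, mean_struggle, mean_immobile, seed = 1L,
                           start_label = c("struggle", "immobility")) {
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(mean_struggle, "mean_struggle", positive = TRUE)
  check_scalar(mean_immobile, "mean_immobile", positive = TRUE)
  start_label <- match.arg(start_label)
  lens <- with_seed(seed, {
    # draw comfortably more bouts than needed, extend if the tail falls short
    out <- numeric(0)
    lab <- character(0)
    cur <- start_label
    total <- 0
    while (total < duration) {
      m <- if (cur == "struggle") mean_struggle else mean_immobile
      len <- stats::rexp(1L, rate = 1 / m)
      out <- c(out, len); lab <- c(lab, cur)
      total <- total + len
      cur <- if (cur == "struggle") "immobility" else "struggle"
    }
    list(len = out, lab = lab)
  })
  offs <- cumsum(lens$len)
  keep <- which(c(0, offs[-length(offs)]) < duration)
  onset <- c(0, offs)[keep]
  offset <- pmin(offs[keep], duration)
  bout_annotation(onset, offset, lens$lab[keep], session_duration = duration)
}

#' Parameters for the abundance-table simulator
#'
#' Defaults emulate a small TMT-style screen: 1000 features, 3 samples per
#' group, 5% planted up- and down-regulated features at fold change 2, and
#' 10% multiplicative log-normal noise.
#'
#' @param n_features number of features.
#' @param n_per_group samples per group (two groups).
#' @param frac_up,frac_down fractions of planted up/down features
#'   (\code{frac_up + frac_down <= 1}).
#' @param effect_fc multiplicative fold change of planted features (> 1).
#' @param noise_cv coefficient of variation of multiplicative log-normal noise.
#' @param base_meanlog,base_sdlog log-normal parameters of per-feature baseline
#'   abundance.
#' @param seed integer RNG seed.
#' @return a validated list of class \code{omics_sim_params}.
#' @export
omics_sim_params <- function(n_features = 1000, n_per_group = 3,
                             frac_up = 0.05, frac_down = 0.05,
                             effect_fc = 2, noise_cv = 0.1,
                             base_meanlog = log(1000), base_sdlog = 1,
                             seed = 1L) {
  check_scalar(n_features, "n_features", positive = TRUE)
  check_scalar(n_per_group, "n_per_group", positive = TRUE)
  if (n_per_group < 2) param_error("'n_per_group' must be >= 2")
  check_scalar(frac_up, "frac_up", nonneg = TRUE)
  check_scalar(frac_down, "frac_down", nonneg = TRUE)
  if (frac_up + frac_down > 1) param_error("'frac_up' + 'frac_down' must be <= 1")
  check_scalar(effect_fc, "effect_fc", positive = TRUE)
  if (effect_fc <= 1) param_error("'effect_fc' must be > 1")
  check_scalar(noise_cv, "noise_cv", nonneg = TRUE)
  structure(list(n_features = as.integer(n_features),
                 n_per_group = as.integer(n_per_group),
                 frac_up = frac_up, frac_down = frac_down,
                 effect_fc = effect_fc, noise_cv = noise_cv,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 seed = as.integer(seed)),
            class = "omics_sim_params")
}

#' Simulate a two-group abundance table with planted effects
#'
#' Planted up-regulated features have an expected treatment/control ratio of
#' \code{effect_fc}; down-regulated features \code{1/effect_fc}. The number of
#' planted features is \code{round(frac * n_features)}, assigned to the lowest
#' feature indices (up first, then down). Noise is multiplicative log-normal
#' with unit mean and coefficient of variation \code{noise_cv}; at
#' \code{noise_cv = 0} empirical fold changes equal the planted values exactly.
#'
#' @param params an \code{\link{omics_sim_params}} object.
#' @return list with \code{table} (an \code{\link{abundance_table}}) and
#'   \code{truth}: named character vector mapping feature id to
#'   \code{"up"}, \code{"down"} or \code{"null"}.
#' @export
simulate_abundance <- function(params) {
  if (!inherits(params, "omics_sim_params")) {
    params <- do.call(omics_sim_params, as.list(params))
  }
  p <- params
  nf <- p$n_features; npg <- p$n_per_group
  n_up <- round(p$frac_up * nf)
  n_down <- round(p$frac_down * nf)
  truth <- rep("null", nf)
  if (n_up > 0) truth[seq_len(n_up)] <- "up"
  if (n_down > 0) truth[n_up + seq_len(n_down)] <- "down"
  fc_vec <- c(up = p$effect_fc, down = 1 / p$effect_fc, null = 1)[truth]
  ids <- sprintf("F%05d", seq_len(nf))
  mat <- with_seed(p$seed, {
    base <- stats::rlnorm(nf, p$base_meanlog, p$base_sdlog)
    expected <- cbind(matrix(base, nf, npg),
                      matrix(base * fc_vec, nf, npg))
    if (p$noise_cv > 0) {
      sdlog <- sqrt(log(1 + p$noise_cv^2))
      noise <- matrix(stats::rlnorm(nf * 2L * npg, -sdlog^2 / 2, sdlog),
                      nf, 2L * npg)
      expected * noise
    } else expected
  })
  groups <- rep(c("control", "treatment"), each = npg)
  colnames(mat) <- c(sprintf("ctrl_%d", seq_len(npg)),
                     sprintf("trt_%d", seq_len(npg)))
  tab <- abundance_table(ids, mat, groups)
  list(table = tab, truth = stats::setNames(truth, ids))
}

#' Simulate a simple undirected network with planted hubs
#'
#' Planted hubs receive exactly their requested degrees: each hub is connected
#' to a random sample of non-hub nodes, and all remaining edges are placed
#' among non-hub node pairs only (hub-hub edges are never created, so planted
#' degrees are exact by construction).
#'
#' @param n_nodes number of nodes (ids \code{g001}, \code{g002}, ...).
#' @param n_edges total number of edges.
#' @param planted_hubs named integer vector: node id -> target degree. Ids not
#'   matching the generated node set are rejected.
#' @param seed integer RNG seed.
#' @return an \code{\link{interaction_network}}.
#' @export
simulate_network <- function(n_nodes, n_edges, planted_hubs = integer(0),
                             seed = 1L) {
  check_scalar(n_nodes, "n_nodes", positive = TRUE)
  check_scalar(n_edges, "n_edges", nonneg = TRUE)
  n_nodes <- as.integer(n_nodes); n_edges <- as.integer(n_edges)
  nodes <- sprintf("g%03d", seq_len(n_nodes))
  hub_ids <- names(planted_hubs)
  if (length(planted_hubs) && (is.null(hub_ids) || !all(hub_ids %in% nodes))) {
    param_error("planted hub ids must name nodes g001..g%03d", n_nodes)
  }
  hub_deg <- as.integer(planted_hubs)
  nonhub <- setdiff(nodes, hub_ids)
  n_nonhub <- length(nonhub)
  if (any(hub_deg < 1L) || any(hub_deg > n_nonhub)) {
    param_error("hub degrees must be between 1 and the number of non-hub nodes (%d)", n_nonhub)
  }
  n_hub_edges <- sum(hub_deg)
  n_rest <- n_edges - n_hub_edges
  max_rest <- n_nonhub * (n_nonhub - 1) / 2
  if (n_rest < 0) param_error("n_edges (%d) smaller than total planted hub degree (%d)", n_edges, n_hub_edges)
  if (n_rest > max_rest) {
    param_error("infeasible: %d filler edges requested but only %d non-hub pairs exist",
                n_rest, max_rest)
  }
  with_seed(seed, {
    from <- character(0); to <- character(0)
    for (i in seq_along(hub_ids)) {
      nb <- sample(nonhub, hub_deg[i])
      from <- c(from, rep(hub_ids[i], hub_deg[i])); to <- c(to, nb)
    }
    if (n_rest > 0) {
      # sample filler edges uniformly from non-hub pairs without replacement
      pairs <- utils::combn(nonhub, 2L)
      pick <- sample(ncol(pairs), n_rest)
      from <- c(from, pairs[1L, pick]); to <- c(to, pairs[2L, pick])
    }
    interaction_network(from, to, nodes = nodes)
  })
}
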