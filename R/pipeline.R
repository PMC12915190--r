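# Umbrella pipeline: validated run configuration, stage execution, run
# manifest. A run is a pure function of (config, seed): identical inputs give
# byte-identical numeric outputs (only the manifest timestamp differs).

known_stage_params <- function() list(
  simulate_photometry = names(formals(photometry_sim_params)),
  simulate_bouts = c("duration", "mean_struggle", "mean_immobile", "seed",
                     "start_label"),
  simulate_omics = names(formals(omics_sim_params)),
  photometry = c("recording", "bouts", "k_sd", "amplitude_floor",
                 "min_separation", "baseline_mode", "window_pre",
                 "window_post", "bout_label"),
  screen = c("table", "groups", "preset", "fc_up", "fc_down", "alpha",
             "p_mode", "var_equal")
)

#' Load and validate a run configuration
#'
#' A config is a named list (or a path to a JSON file; YAML is accepted when
#' the \pkg{yaml} package is installed) with top-level keys \code{stages}
#' (list of stage entries, each with a \code{stage} name plus stage
#' parameters), \code{out_dir}, optional \code{seed} (default 1) and
#' \code{log_level}. Unknown top-level or stage keys are rejected before any
#' stage runs.
#'
#' @param config named list or file path.
#' @return validated config list of class \code{run_config}.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        param_error("YAML config requires the 'yaml' package; use JSON")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    }
  }
  if (!is.list(config)) param_error("config must be a named list or file path")
  allowed <- c("stages", "out_dir", "seed", "log_level")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    param_error("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  if (is.null(config$out_dir)) param_error("config needs 'out_dir'")
  if (is.null(config$stages) || !length(config$stages)) {
    param_error("config needs a non-empty 'stages' list")
  }
  if (is.null(config$seed)) config$seed <- 1L
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$stage)) param_error("stage %d has no 'stage' name", i)
    if (!st$stage %in% names(known_stage_params())) {
      param_error("unknown stage '%s' (stage %d)", st$stage, i)
    }
    bad <- setdiff(names(st), c("stage", known_stage_params()[[st$stage]]))
    if (length(bad)) {
      param_error("unknown key(s) in stage '%s': %s", st$stage,
                  paste(bad, collapse = ", "))
    }
    ins <- intersect(names(st), c("recording", "bouts", "table", "groups"))
    for (k in ins) {
      if (is.character(st[[k]]) && !st[[k]] %in% c("previous") &&
          !file.exists(st[[k]])) {
        param_error("stage '%s': input file '%s' does not exist", st$stage, st[[k]])
      }
    }
  }
  structure(config, class = "run_config")
}

#' Execute a pipeline run
#'
#' Stages run in declared order; each output file lands in \code{out_dir} and
#' a \code{manifest.json} records package version, timestamp, resolved
#' parameters, input checksums and seed. Stage inputs given as
#' \code{"previous"} resolve to the matching output of an earlier simulate
#' stage.
#'
#' @param config a \code{\link{run_config}} (or anything it accepts).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) param_error("cannot create out_dir '%s'", out_dir)
  prev <- list()   # outputs of earlier stages available as "previous"
  resolved <- list()
  checksums <- character(0)
  add_checksum <- function(path) {
    checksums[basename(path)] <<- unname(tools::md5sum(path))
  }
  resolve_input <- function(val, key) {
    if (identical(val, "previous")) {
      if (is.null(prev[[key]])) {
        param_error("no earlier stage produced a '%s' output", key)
      }
      prev[[key]]
    } else val
  }
  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    pars <- st[setdiff(names(st), "stage")]
    if (st$stage %in% c("simulate_photometry", "simulate_bouts",
                        "simulate_omics") && is.null(pars$seed)) {
      pars$seed <- cfg$seed
    }
    if (st$stage == "simulate_photometry") {
      sim <- simulate_photometry(do.call(photometry_sim_params, pars))
      rec_path <- file.path(out_dir, sprintf("stage%02d_recording.csv", i))
      write_photometry_csv(sim$recording, rec_path)
      gt_path <- file.path(out_dir, sprintf("stage%02d_ground_truth.tsv", i))
      utils::write.table(sim$events, gt_path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      add_checksum(rec_path); add_checksum(gt_path)
      prev$recording <- rec_path
      prev$ground_truth <- sim$events
    } else if (st$stage == "simulate_bouts") {
      b <- do.call(simulate_bouts, pars)
      b_path <- file.path(out_dir, sprintf("stage%02d_bouts.tsv", i))
      write_bouts_tsv(b, b_path)
      add_checksum(b_path)
      prev$bouts <- b_path
    } else if (st$stage == "simulate_omics") {
      sim <- simulate_abundance(do.call(omics_sim_params, pars))
      t_path <- file.path(out_dir, sprintf("stage%02d_abundance.tsv", i))
      g_path <- file.path(out_dir, sprintf("stage%02d_groups.tsv", i))
      tr_path <- file.path(out_dir, sprintf("stage%02d_truth.tsv", i))
      write_table_tsv(sim$table, t_path, g_path)
      utils::write.table(data.frame(feature_id = names(sim$truth),
                                    truth = unname(sim$truth)),
                         tr_path, sep = "\t", row.names = FALSE, quote = FALSE)
      add_checksum(t_path); add_checksum(g_path); add_checksum(tr_path)
      prev$table <- t_path; prev$groups <- g_path
    } else if (st$stage == "photometry") {
      rec_path <- resolve_input(pars$recording %||% "previous", "recording")
      rec <- read_photometry_csv(rec_path)
      add_checksum(rec_path)
      det_pars <- pars[intersect(names(pars),
                                 c("k_sd", "amplitude_floor",
                                   "min_separation", "baseline_mode"))]
      dp <- do.call(event_detection_params, det_pars)
      trace <- compute_dff(rec)
      ev <- detect_events(trace, dp)
      write_events_tsv(ev, file.path(out_dir, sprintf("stage%02d_events.tsv", i)))
      write_summary_json(summarize_events(ev),
                         file.path(out_dir, sprintf("stage%02d_summary.json", i)))
      if (!is.null(pars$bouts)) {
        b_path <- resolve_input(pars$bouts, "bouts")
        bouts <- read_bouts_tsv(b_path,
                                session_duration = length(rec$time) / rec$sampling_rate)
        add_checksum(b_path)
        z <- zscore_trace(trace)
        pem <- extract_peri_event(z, bouts,
                                  label = pars$bout_label %||% "struggle",
                                  window_pre = pars$window_pre %||% 2,
                                  window_post = pars$window_post %||% 6)
        write_peri_matrix_csv(pem, file.path(out_dir,
                                             sprintf("stage%02d_peri_event.csv", i)))
      }
      prev$events <- ev
    } else if (st$stage == "screen") {
      t_path <- resolve_input(pars$table %||% "previous", "table")
      g_path <- resolve_input(pars$groups %||% "previous", "groups")
      tab <- read_table_tsv(t_path, g_path)
      add_checksum(t_path); add_checksum(g_path)
      thr <- if (!is.null(pars$preset)) screen_preset(pars$preset) else
        screen_thresholds(pars$fc_up %||% 1.1, pars$fc_down %||% 0.9,
                          pars$alpha %||% 0.05, pars$p_mode %||% "raw")
      stats_df <- classify_features(
        compute_feature_stats(tab, var_equal = pars$var_equal %||% TRUE), thr)
      utils::write.table(stats_df,
                         file.path(out_dir, sprintf("stage%02d_stats.tsv", i)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_summary_json(summarize_screen(stats_df),
                         file.path(out_dir, sprintf("stage%02d_summary.json", i)))
    }
    resolved[[i]] <- c(list(stage = st$stage), pars)
  }
  manifest <- list(
    package = "photomics",
    version = as.character(utils::packageVersion("photomics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    stages = resolved,
    input_checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
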