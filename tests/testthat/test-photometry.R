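test_that("control-channel fit solves the normal equations", {
  fs <- 20
  x <- 100 + sin(seq(0, 10, length.out = 201))
  # identity: signal == control
  rec <- photometry_recording(x, x, fs)
  fit <- fit_control_channel(rec)
  expect_equal(fit$a, 0, tolerance = 1e-10)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$fitted, rec$f_signal, tolerance = 1e-12)
  expect_equal(fit$residual_rms, 0, tolerance = 1e-10)

  # exact affine relation recovers (a, b) = (1, 2)
  rec2 <- photometry_recording(2 * x + 1, x, fs)
  fit2 <- fit_control_channel(rec2)
  expect_equal(fit2$a, 1, tolerance = 1e-8)
  expect_equal(fit2$b, 2, tolerance = 1e-10)

  # degenerate/invalid inputs
  expect_error(fit_control_channel(photometry_recording(x, rep(5, 201), fs)),
               class = "photomics_data_error")
  xx <- x; xx[3] <- NaN
  expect_error(fit_control_channel(photometry_recording(xx, x, fs)),
               class = "photomics_data_error")
})

test_that("dff follows the printed formula and vanishes under a perfect fit", {
  fs <- 20
  x <- 100 + sin(seq(0, 10, length.out = 201))
  # direct evaluation: f_signal 110 against fitted 100 gives dff 0.10
  rec <- photometry_recording(rep(110, 201), x, fs)
  fit <- structure(list(a = 100, b = 0, fitted = rep(100, 201),
                        residual_rms = 0), class = "control_fit")
  tr <- compute_dff(rec, fit)
  expect_equal(tr$dff, rep(0.10, 201))

  # perfect-fit invariance: affinely related channels give dff identically 0
  rec2 <- photometry_recording(3 * x + 7, x, fs)
  tr2 <- compute_dff(rec2)
  expect_lt(max(abs(tr2$dff)), 1e-10)

  # non-positive fitted control is a domain error listing indices
  bad_fit <- structure(list(a = 0, b = 0, fitted = rep(0, 201),
                            residual_rms = 0), class = "control_fit")
  expect_error(compute_dff(rec, bad_fit), class = "photomics_data_error")
})

test_that("dff recovers the planted transient sum on simulated recordings", {
  # seed 11 realizes 4 transients at rate 0.5/min; shared 5% artifact and
  # small channel noise; correlation with the ground-truth kernel sum > 0.95
  p <- photometry_sim_params(duration = 600, event_rate = 0.5,
                             artifact_sd = 0.05, noise_sd = 0.02, seed = 11)
  sim <- simulate_photometry(p)
  expect_gte(nrow(sim$events), 3)
  tr <- compute_dff(sim$recording)
  t <- sim$recording$time
  gt <- rowSums(vapply(seq_len(nrow(sim$events)), function(i) {
    d <- t - sim$events$onset_s[i]
    a <- sim$events$amplitude[i]
    ifelse(d < 0, 0,
           ifelse(d < p$rise_time, a * d / p$rise_time,
                  a * exp(-(d - p$rise_time) / p$decay_tau)))
  }, numeric(length(t))))
  expect_gt(stats::cor(tr$dff, gt), 0.95)
})

test_that("z-scoring uses whole-trace mean and denominator-N SD", {
  tr <- make_trace(c(1, 2, 3))
  z <- zscore_trace(tr)
  # hand computation: mean 2, population SD sqrt(2/3)
  expect_equal(z$z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(z$mean_used, 2)
  expect_equal(z$sd_used, sqrt(2 / 3))

  # normalization identity on arbitrary traces
  for (s in 1:5) {
    y <- with_seed_test(s, stats::rnorm(500, 3, 2))
    zz <- zscore_trace(make_trace(y))
    expect_lt(abs(mean(zz$z)), 1e-10)
    expect_lt(abs(sqrt(mean(zz$z^2)) - 1), 1e-10)
  }
  expect_error(zscore_trace(make_trace(rep(1, 10))),
               class = "photomics_data_error")
})

test_that("peri-event extraction uses exact index arithmetic and drops short windows", {
  fs <- 20
  y <- seq_len(401) / 100          # 20 s ramp, distinguishable values
  z <- structure(list(z = y, time = (0:400) / fs, sampling_rate = fs),
                 class = "zscored_trace")
  bouts <- bout_annotation(onset = c(1, 10), offset = c(2, 11),
                           label = c("struggle", "struggle"),
                           session_duration = 20.05)
  m <- extract_peri_event(z, bouts, "struggle", window_pre = 2, window_post = 6)
  # bout at t = 1 s cannot host a 2 s pre-window: dropped and counted
  expect_equal(nrow(m$values), 1)
  expect_equal(m$n_dropped, 1)
  expect_equal(ncol(m$values), 161)   # round((2+6)*20) + 1
  # the row is exactly the samples for t in [8, 16]
  expect_equal(as.numeric(m$values[1, ]), y[161:321])
  expect_equal(m$relative_time[1], -2)
  expect_equal(m$relative_time[161], 6)
  expect_equal(m$relative_time[41], 0)

  # constant-zero trace gives all-zero rows
  z0 <- structure(list(z = rep(0, 401), time = (0:400) / fs,
                       sampling_rate = fs), class = "zscored_trace")
  m0 <- extract_peri_event(z0, bouts, "struggle")
  expect_true(all(m0$values == 0))

  # no qualifying bouts is an error carrying the drop count
  early <- bout_annotation(0.5, 1, "struggle", 20.05)
  expect_error(extract_peri_event(z, early, "struggle"),
               class = "photomics_data_error")
})

test_that("peri-event means average the requested sub-window", {
  fs <- 20
  # synthetic step: z = 2 after onset at t = 10, 0 before
  tvec <- (0:400) / fs
  z <- structure(list(z = ifelse(tvec >= 10, 2, 0), time = tvec,
                      sampling_rate = fs), class = "zscored_trace")
  b <- bout_annotation(10, 12, "struggle", 20.05)
  m <- extract_peri_event(z, b, "struggle", window_pre = 2, window_post = 6)
  r <- mean_peri_event_z(m, 0, 6)
  expect_equal(r$grand_mean, 2)
  expect_equal(r$per_trial, 2)
  # pre-onset window averages the zero phase (excluding the onset sample)
  r_pre <- mean_peri_event_z(m, -2, -1 / fs)
  expect_equal(r_pre$grand_mean, 0)
  expect_error(mean_peri_event_z(m, 0, 10), class = "photomics_param_error")
  # all-zero matrix gives all-zero means
  m$values[] <- 0
  expect_equal(mean_peri_event_z(m, 0, 6)$grand_mean, 0)
})
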