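# photomics

Analysis toolkit for two kinds of data that often appear together in
stress-neurobiology studies:

1. **Dual-channel fiber-photometry recordings** of calcium or glutamate
   sensors (GCaMP, iGluSnFR): a 470 nm sensor-dependent channel and a 410 nm
   isosbestic control channel recorded simultaneously. The package implements
   the standard correction and quantification pipeline — least-squares fit of
   the control to the signal channel, ΔF/F, z-scoring, peri-event analysis
   around behavioral bout onsets, and threshold-based transient detection with
   per-event metrics.
2. **Two-group omics abundance tables** (proteomic, phosphoproteomic, or
   transcriptomic): a fold-change + t-test differential-expression screen with
   the field's conventional thresholds, screen summaries, gene-set
   intersection, hypergeometric enrichment factors, and degree-based hub
   ranking on interaction networks.

Seeded synthetic-data generators with known ground truth (photometry traces
with photobleaching, shared motion artifacts and Poisson-timed transients;
abundance tables with planted fold changes; networks with planted hubs) make
every stage testable without any external data.

## The core quantities

* **ΔF/F** — with `fitted = a + b·F410` the least-squares fit of the control
  channel to the signal channel, `x = ΔF/F = (F470 − fitted) / fitted`.
* **Z score** — `z = (x − mean) / sd`, whole-trace mean and population
  (denominator-N) SD.
* **Transient detection** — an event is a maximal run of samples with
  `ΔF/F > baseline mean + k·SD` (default `k = 3`) whose peak also reaches the
  amplitude floor (default 0.02, i.e. 2% ΔF/F). Per event: frequency
  (events/min), AUC (trapezoidal integral above baseline), and decay time
  constant τ from a bounded single-exponential fit `A·exp(−t/τ) + C`.
* **Screen** — per feature, fold change `FC = mean(treatment)/mean(control)`
  (raw scale) and a two-sided pooled-variance Student's t-test;
  `up` iff `FC > fc_up` and `p < α`, `down` iff `FC < fc_down` and `p < α`
  (proteomic preset 1.1/0.9/0.05; phospho 1.2/0.83/0.05).
* **Enrichment factor** — `k/M`: of `M` detected pathway members, the fraction
  `k` that are differential; tail probability from the hypergeometric
  distribution, `P(X ≥ k)`.

## Worked example

```r
library(photomics)

# --- photometry: simulate 10 min at 20 Hz, 2 transients/min, then analyze ---
sim    <- simulate_photometry(photometry_sim_params(duration = 600,
            event_rate = 2, noise_sd = 0.1, seed = 42))   # 26 true events
trace  <- compute_dff(sim$recording)                      # isosbestic ΔF/F
events <- detect_events(trace, event_detection_params())
summarize_events(events)
#> event_summary: 25 events in 10.00 min (2.500 events/min); mean AUC 0.02477, mean tau 0.717 s

bouts <- simulate_bouts(600, mean_struggle = 5, mean_immobile = 10, seed = 42)
z     <- zscore_trace(trace)
pem   <- extract_peri_event(z, bouts, "struggle", window_pre = 2, window_post = 6)
pem
#> peri_event_matrix: 35 trial(s) x 161 timepoints, window [-2, +6] s (1 dropped)
mean_peri_event_z(pem, 0, 6)$grand_mean
#> 0.057

# --- omics screen: printed-count arithmetic and a simulated screen ---
summarize_screen(7190, n_up = 157, n_down = 114)
#> screen_summary: 7190 identified; 157 up (2.18%), 114 down (1.59%); 271 DEPs total

om <- simulate_abundance(omics_sim_params(n_features = 2000, frac_up = 0.05,
                                          frac_down = 0.05, seed = 42))
cl <- classify_features(compute_feature_stats(om$table), screen_preset("proteomic"))
summarize_screen(cl)
#> screen_summary: 2000 identified; 148 up (7.40%), 130 down (6.50%); 278 DEPs total

deps <- names(om$truth)[cl$cls != "ns"]
pw   <- gene_set("planted", names(om$truth)[om$truth != "null"], "simulator")
enrichment_test(deps, pw, names(om$truth))
#> enrichment_result [planted]: k=200 of M=200 pathway members among n=278 differential (N=2000); factor 1.0000, P = 3.502e-211

net <- simulate_network(40, 80, planted_hubs = c(g007 = 20L), seed = 42)
rank_hubs(net, top_k = 3)
#>     id degree
#> 1 g007     20
#> 2 g026     10
#> 3 g040      8
```

25 of 26 planted transients are recovered at this signal-to-noise ratio (one
pair of onsets falls inside the merge window); the event frequency, AUC, and
τ ≈ 0.7–0.9 s estimates are per-event fits against the planted τ = 1 s under
noise. At the default channel noise (1% of baseline) a 5% ΔF/F transient sits
near the detection limit — see the methods vignette for what the simulator
does and does not emulate.

## Command line

```sh
Rscript inst/cli/photomics.R simulate --what photometry --out-prefix demo --seed 1
Rscript inst/cli/photomics.R photometry --recording demo_recording.csv --out-dir out
Rscript inst/cli/photomics.R screen --table T.tsv --groups G.tsv --preset proteomic --out-dir out
Rscript inst/cli/photomics.R hubs --edges E.tsv --top 9
```

(After installation the script is at
`system.file("cli", "photomics.R", package = "photomics")`.)

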