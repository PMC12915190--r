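---
title: "photomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{photomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photomics)
```

This vignette is the package's own account of the methods it implements: the
models and their assumptions, the tunable parameters with their defaults and
units, what the synthetic-data generators emulate (and deliberately do not),
the numerical choices, and the decisions made where the conventions of the
field leave the design genuinely open. It states no empirical result that the
test suite does not itself compute.

## 1. The photometry model

A dual-channel recording consists of a sensor-dependent 470 nm channel
$F_{470}(t)$ and an isosbestic 410 nm control channel $F_{410}(t)$, sampled
uniformly. At the isosbestic wavelength the sensor's fluorescence is
independent of analyte binding, so the control channel carries only the
nuisance terms — motion artifacts, photobleaching, autofluorescence — that are
(to first order) shared with the signal channel.

**Control fit.** The control is mapped onto the signal channel by ordinary
least squares over the whole recording:
$\widehat{F}(t) = a + b\,F_{410}(t)$, with $(a, b)$ minimizing
$\sum_i (F_{470,i} - a - b F_{410,i})^2$. A whole-recording affine fit is the
simplest member of the family of control-scaling methods in use; it assumes
that bleaching and artifacts scale *proportionally* between channels. A
robust (Huber) variant is available via `fit_control_channel(method =
"robust")`, but OLS is the tested default. When the two channels bleach at
different rates an affine map cannot track the time-varying ratio and a slow
residual drift remains in ΔF/F; this is a documented limitation of the model
class, not of the implementation (see §3).

**ΔF/F and z-score.**
$$x(t) = \Delta F/F = \frac{F_{470}(t) - \widehat{F}(t)}{\widehat{F}(t)},
\qquad z(t) = \frac{x(t) - \bar{x}}{\mathrm{sd}(x)}.$$
The mean and SD are whole-trace statistics, and the SD uses the *population*
(denominator-$N$) form, so `zscore_trace` output has mean 0 and SD 1 exactly.
An exact affine relation between the channels gives $x \equiv 0$; the suite
asserts $|x| < 10^{-10}$ in that case.

**Transient detection.** The threshold is
$T = \mu_b + k\,\sigma_b$ with $k = 3$ by default. An event is a maximal run
of samples with $x > T$; its onset is the first sample above $T$ and its end
the first return below $T$ (or the trace end). Runs separated by less than
`min_separation` (default 0.5 s) are merged, then events whose peak falls
below the amplitude floor are discarded. Per event we report the peak
amplitude, the trapezoidal AUC of $x - \mu_b$ over the event span (floored at
0), and the decay constant of §2.

Two conventions in this criterion are not fixed by common usage and are
therefore explicit parameters:

* **Units of the amplitude floor.** The conventional "ΔF/F ≥ 2" cutoff is
  read as **2 percent** (`amplitude_floor = 0.02` on the ratio scale): ΔF/F
  is a ratio, and a ratio of 2 (200%) is physiologically implausible for
  GCaMP/iGluSnFR transients. Event tables report both `peak_amp` (ratio) and
  `peak_amp_pct` so either reading can be checked, and the floor is a
  parameter so the literal reading (`amplitude_floor = 2`) is attainable.
* **What "baseline" means.** Default: whole-trace mean and SD of ΔF/F
  (`baseline_mode = "whole_trace"`). At high event rates the transients
  inflate these statistics ("self-contamination"); the
  `"iterative_exclusion"` mode re-estimates the baseline twice after
  excluding super-threshold samples and is the appropriate choice for busy
  traces. Whether baselines should be per-session or per-behavioral-epoch is
  left open in the conventions we follow; whole-session is the default and
  per-epoch analysis can be composed from `extract_peri_event`.

**Peri-event analysis.** Windows of $[-2, +6]$ s (defaults) around bout
onsets of a chosen label; the post-onset extent matches the common
"within six seconds of event onset" quantification window, the pre side is a
display/baseline choice. Rows whose window would leave the recording are
dropped and counted, never padded. `mean_peri_event_z` averages an inclusive
sub-window per trial and then across trials.

## 2. Decay-constant fitting

For each event the segment from peak to end is fit with
$y(t) = A e^{-t/\tau} + C$ by least squares. Initialization: $C_0$ from the
segment tail, $A_0 = y(0) - C_0$, $\tau_0 = t_{1/2}/\ln 2$ from the
time-to-half-peak. Positivity of $\tau$ is enforced by optimizing over
$\log\tau$ (BFGS, relative tolerance $10^{-12}$); this is equivalent to a
bounded fit without the boundary pathologies. Failures — segments shorter
than 5 samples, non-decaying segments, optimizer errors — yield `tau = NA`
with the event retained. The suite checks exact recovery on noiseless
exponentials ($|\hat\tau - \tau| < 10^{-4}$), 5% median accuracy at 10%
amplitude noise over 200 replicates, and the analytic identity
$\int_0^{10\tau} A e^{-t/\tau} dt \approx A\tau$ within 2%.

## 3. What the simulator states, and what it does not

`simulate_photometry` generates
$$F_{410}(t) = B\, e^{-t/\tau_c} (1 + a(t)) + \varepsilon_c(t), \qquad
  F_{470}(t) = B\, e^{-t/\tau_s} (1 + a(t)) (1 + \textstyle\sum_j K_j(t)) +
  \varepsilon_s(t),$$
with baseline $B$ (default 100 a.u.), exponential photobleaching, a shared
artifact $a(t)$, per-channel white Gaussian noise, and transient kernels
$K_j$: linear rise over `rise_time` (default 0.1 s) to an amplitude drawn
from $N(0.05, 0.01)$ truncated at 0, then exponential decay with
$\tau = 1$ s. Onsets are a homogeneous Poisson process (default 6/min);
overlapping transients sum additively. The artifact is a Gaussian random walk
passed through a single-pole low-pass filter (cutoff 0.1 Hz) and rescaled to
`artifact_sd` (default 0.02) — shared *identically* by both channels before
channel noise, which is precisely the assumption isosbestic correction rests
on. All randomness comes from one seeded generator per call; the caller's RNG
state is untouched, and identical parameters give bit-identical output.

Defaults that the emulated class of recordings does not pin down were chosen
once and flagged: sampling rate 20 Hz, channel noise 1% of baseline, and
**equal bleaching constants** ($\tau_s = \tau_c = 1500$ s). The last is
deliberate: the affine control fit of §1 assumes proportional bleaching, so
the stated world of the generator satisfies the model the pipeline fits.
Unequal constants are fully supported as parameters and produce the realistic
residual-drift failure mode described in §1 — useful for studying the
pipeline's limits, but not part of the default recovery tests. Note also that
at the default 1% noise a 5% ΔF/F transient has a single-sample SNR of ~3.5
and detection is imperfect; recovery tests therefore state their noise level
explicitly.

Not emulated, by design: sinusoidal LED modulation and demodulation,
hemodynamic contamination, sensor binding kinetics (transients are ideal
kernels), pink/drift noise beyond the filtered-walk artifact, and any
behavior-to-signal coupling (bout annotations are simulated independently of
the trace). A green recovery test therefore establishes that the pipeline
inverts the stated generative model — not that it would be unbiased on a real
recording with unmodeled physiology.

`simulate_bouts` tiles $[0, T)$ with alternating exponential bout lengths;
`simulate_abundance` plants `round(frac * n_features)` effects (lowest
feature indices, up before down) with log-normal baselines
($e^{\mu}=1000$ a.u., $\sigma_{\log}=1$) and unit-mean log-normal noise of a
stated CV; `simulate_network` gives planted hubs their exact degrees by
connecting hubs only to non-hub nodes and placing filler edges among non-hub
pairs (hub–hub edges never occur — exactness by construction; consequently
the non-hub pair pool must be large enough, which is validated). The filler
sampler enumerates non-hub pairs, which is fine for the network sizes the
screen ranks (hundreds of nodes), not for genome-scale graphs.

## 4. The differential-expression screen

Fold change is the **raw ratio** of group means, matching how "1.1-fold
change" thresholds are printed in proteomic screens; the asymmetric printed
bounds (0.9 rather than $1/1.1$; 0.83 ≈ $1/1.2$) are taken literally. The
test is a two-sided pooled-variance Student's t (Welch via
`var_equal = FALSE`); Benjamini–Hochberg adjustment is computed across all
features, and `p_mode` selects raw vs adjusted p for classification.
Zero-variance features with equal means get $p = 1$ (flagged `degenerate`);
with unequal means the t statistic is infinite and $p = 0$, which is the
correct noiseless limit and makes noiseless planted-effect recovery exact.

The **transcript preset** (FC 1.2/0.83, BH-adjusted $p < 0.01$) is a generic
stand-in for count-model DEG calling: this package does not implement a
negative-binomial dispersion model, and transcriptomic DEG counts from such
models are not reproduction targets here — only their additive consistency
(up + down = total) is asserted.

Percentages in `summarize_screen` are rounded **half away from zero** to two
decimals (base R's `round` is banker's rounding); comparisons against values
printed to one decimal round to the printed precision.

**Enrichment factor.** Defined as $k/M$ — the fraction of the $M$ detected
pathway members that are differential — which is bounded by 1 and consistent
with factors like 0.61 reported as ratios ≤ 1 in the screens this package
emulates. This is a recorded assumption: "enrichment factor" has no single
field-wide definition (some tools print $\frac{k/n}{M/N}$). The tail
probability is the upper hypergeometric tail
$P(X \ge k) = \sum_{i=k}^{\min(M,n)} \binom{M}{i}\binom{N-M}{n-i} /
\binom{N}{n}$, computed via `stats::phyper` and verified in the suite against
direct enumeration for every configuration with $N \le 15$. With $M = 0$ the
factor is reported as 0 and flagged `empty_pathway`.

**Identifier dialect.** Before any set operation, ids are upper-cased and a
trailing `.digits` version suffix is stripped. **Hub ranking** is plain
degree centrality with lexicographic tie-breaks; "significant connectivity"
has no standard definition, so the ranking is the transparent primitive and
`top_k` (default 9, the usual size of reported hub-gene panels) is a
parameter.

## 5. IO and reproducibility

Dialects are pinned, not sniffed: UTF-8, LF, `.` decimal, no quoting;
recording CSV header `time_s,f470,f410` with uniform time enforced at
$10^{-6}$ relative tolerance; bouts/edges/abundance as TSV; gene sets as GMT
(`name<TAB>source<TAB>ids...`). Intervals are half-open `[onset, offset)` in
seconds; sample $i$ covers time $t_i$. Readers name the offending line in
validation errors; duplicate ids/edges are deduplicated with warning counts,
while self-loops and non-positive abundances are hard errors. Every
`run_pipeline` output directory carries a `manifest.json` with package
version, timestamp, resolved parameters (so no defaulted decision is silent),
input checksums and seed; a run is a pure function of (config, seed) up to
the manifest timestamp. Unknown config keys are rejected before any stage
runs. JSON configs are always supported; YAML only when the `yaml` package is
installed.

## 6. Known limitations

* The affine control fit leaves residual drift under channel-specific
  bleaching rates (§1, §3); detrending or time-varying fits are out of scope.
* Detection merges transients closer than the supra-threshold time plus
  `min_separation`; at 6 events/min this collapses ~15–20% of Poisson event
  pairs, so raw-rate recovery is bounded away from 100% *by the method* — the
  recovery suite tests against the merge-corrected expectation
  $\lambda\, e^{-\lambda t_{\mathrm{res}}}$ rather than pretending otherwise.
* The t-test screen assumes approximate normality on the raw abundance
  scale; no log-transform is applied because fold-change thresholds are
  defined on the raw ratio. For count data use a dedicated count model.
* No group-level inferential statistics (ANOVA etc.) are provided; the
  package quantifies signals, it does not compare cohorts.
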