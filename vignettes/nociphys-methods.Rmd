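---
title: "Quantifying nociceptor-like neuron physiology with nociphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nociceptor-like neuron physiology with nociphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nociphys)
```

## What this package computes

Stem-cell-derived nociceptor-like neurons are characterized functionally
along four axes, and `nociphys` implements the quantification for each:

1. **Passive membrane properties** from voltage-clamp capacitive
   transients: input/series resistance and whole-cell capacitance.
2. **Action-potential (AP) features** from current-clamp traces:
   half-width, afterhyperpolarization (AHP) amplitude and recovery time
   constant, and the repolarization "shoulder" typical of some
   nociceptors.
3. **Mechanically-activated currents**: biexponential inactivation fits,
   classification into rapidly (RA), intermediate (IA) and slowly (SA)
   adapting classes, responder criteria, and Fisher's exact comparison of
   responder tables.
4. **Calcium-imaging populations**: agonist responder calling, the
   peak-6/peak-4 sensitization statistic, and temperature-response
   matrices.

A fifth, transcriptomic axis summarizes a bulk RNA-seq count matrix:
median-of-ratios size factors, marker-relative expression (relative to the
pan-sensory marker ISL1), replicate averaging and per-gene center-scaling
for heatmap display.

Every analysis has a synthetic counterpart in the `sim_*()` generators, so
each stage is validated by parameter recovery: generate data with known
ground truth, run the analysis, compare.

## The capacitance recipe and its bias

A cell patched through a pipette with series (access) resistance $R_s$ and
membrane resistance $R_{in}$, capacitance $C_m$, responds to a voltage
step $\Delta V$ (here $-15$ mV for 100 ms; 25 sweeps are averaged) with a
current that jumps instantaneously to $\Delta V / R_s$ and decays with
$\tau = C_m (R_s \| R_{in})$ toward $\Delta V / (R_s + R_{in})$.

The recipe implemented by `passive_properties()`:

* resistance from the transient peak relative to the pre-step baseline,
  $R = |\Delta V / I_{peak}|$ — in this circuit that estimates $R_s$;
* a biexponential fit of the decay (window: from the sample after the
  peak to five seed time constants later) whose amplitude-weighted
  constant $\tau_w = \sum |A_i| \tau_i / \sum |A_i|$ estimates $\tau$;
* $C_m = \tau_w / R$, with ms/M$\Omega$ = nF bookkeeping.

Because $\tau = C_m R_s R_{in}/(R_s + R_{in})$ and the peak estimates
$R_s$, the ratio recovers $C_m \cdot R_{in}/(R_s+R_{in})$: exact as
$R_{in} \gg R_s$, biased low by $\approx R_s/R_{in}$ otherwise. A
property test sweeps this ratio; the bias is under 2% whenever
$R_{in}/R_s \ge 50$, which holds for the cells this method is used on
(e.g. $R_s \sim 5$ M$\Omega$, $R_{in}$ hundreds of M$\Omega$). The
"relative current of the first capacitive transient" is deliberately read
as peak-minus-baseline (not peak-minus-steady-state): that is the reading
under which $\tau/R$ equals $C_m$. Both resistance estimates
(`r_input_mohm` from the peak, `r_steady_mohm` from the fitted steady
state, which approximates $R_s + R_{in}$) are reported so users can audit
the distinction.

```{r capacitance}
g <- sim_capacitive_sweeps(20, 5, 500, v_step_mv = -15, n_sweeps = 25,
                           cfg = sim_config(seed = 1, fs = 1e5,
                                            duration = 0.12))
passive_properties(g$sweeps, v_step_mv = -15)
```

## AP features

`detect_aps()` defines an AP by its upstroke: the smoothed derivative
crossing 10 mV/ms (configurable) marks the threshold; the following
voltage maximum (refined on the raw trace) is the peak; crossings whose
peak rises less than 20 mV above threshold are rejected as noise, and a
2 ms refractory window suppresses double counts. The trace is zero-phase
low-pass filtered (5 kHz, or fs/4 when sampling is slower) before the
derivative; zero-phase (forward-backward) filtering is used throughout the
package so feature latencies are unbiased.

* **Half-width** — width at 50% of the threshold-to-peak amplitude, with
  linear interpolation on both flanks. The 50% reference is the standard
  convention; the measurement itself is shown graphically in most papers
  without a formula.
* **AHP** — the voltage minimum within 20 ms after the peak. Its recovery
  constant $\tau_{AHP}$ comes from a monoexponential fit of exactly 32 ms
  starting at that minimum, and is reported only when the AHP amplitude is
  at least 0.1 mV and no second AP falls inside the window — otherwise the
  feature is absent, not an error.
* **Shoulder** — a monoexponential is fitted between the AP peak and the
  AHP minimum; the shoulder index is the largest positive residual (data
  bulging above the fit) divided by the AP amplitude. Both the continuous
  index and a binary call are reported, since either may be wanted. The
  call threshold defaults to 0.03: on the synthetic template the index
  stays below 0.02 for shoulder-free APs at 0.5 mV noise (the residual
  floor comes from waveform discretization and filtering) and above 0.046
  for a 30% slow-component shoulder, so 0.03 sits in the gap and separates
  the two perfectly. The threshold is tunable for real recordings.

The synthetic AP is a parametric template, not a conductance model: linear
upstroke, exponential repolarization with an optional additive slow
component (10x slower, weight `shoulder_frac`), truncation at the AHP
minimum, monoexponential recovery. The fast repolarization constant is
solved numerically so the half-width is held at its nominal value whatever
the shoulder weight — this keeps half-width recovery and shoulder calling
independently testable. A template suffices because the features being
tested are waveform measurements, not mechanistic quantities.

## Mechanically-activated currents

`fit_inactivation()` low-pass filters at 1 kHz (the analysis bandwidth of
such recordings), fixes the fit asymptote to the pre-stimulus baseline
mean, and fits a biexponential from the post-stimulus peak. Numerical
choices that matter:

* The fit window starts ~1.5/cutoff past the filtered peak: a zero-phase
  filter smears the step onset, but past the transient a filtered
  exponential is again an exact exponential with the same $\tau$, so
  skipping the smeared stretch removes the bias at the cost of amplitude,
  which is then recovered by extrapolating each component back to the
  stimulus onset.
* Component amplitudes are constrained to the sign of the current
  (inactivation is a monotone decay; opposite-sign pairs are a symptom of
  overfitting), taus are bounded above by 20 fit-window spans, and
  components that carry less than 5% of the amplitude or that would have
  decayed away before the window begins are excluded from the weighted
  constant — they absorb residual baseline noise, not current.
* The baseline window excludes the final 2/cutoff seconds before the
  stimulus, where the non-causal filter leaks the response backwards.

Classification follows the weighted constant: RA < 10 ms, IA 10–30 ms,
SA > 30 ms, with boundary values assigned to IA (the published bins are
open at the edges only in floating point). Responder criteria: human cells
are mechanically active when any indentation of at most 10 µm evokes an
inward current beyond −40 pA (inward-negative convention); mouse cells
when the maximum evoked current over the 10-step, 1 µm-increment series
exceeds 50 pA in magnitude, with cells that detached mid-series excluded.
A recording whose post-stimulus baseline departs from the fitted decay by
more than 3 pre-stimulus SDs is flagged as leak-contaminated. Whether a
cell must exhaust the full step series before being called a
non-responder is not specified by the criteria as published; here any
qualifying step suffices for a responder call.

`fisher_exact()` computes the two-sided p by hypergeometric enumeration
over all tables with the observed margins (the test suite checks it
against an independent factorial enumeration for every table with
$N \le 40$, and against `stats::fisher.test`).

## Calcium imaging

Traces are Fura-2-style ratios (or $\Delta F/F_0$ with $F_0$ the
pre-first-stimulus mean). Per-epoch response amplitudes are local: the
signal maximum over the epoch window (extended 30 s past the epoch end to
catch slow transients, truncated at the next epoch) minus the mean over
the 10 s before the onset.

* **Responder calling** — an epoch responds when its amplitude exceeds
  both 3 baseline SDs and an absolute floor of 0.05 ratio units. Neither
  threshold is published for this assay; both are package choices, set
  conservatively and exposed as arguments. Cells failing the terminal
  high-K depolarization are not neurons and are excluded from all
  denominators — consistent with using high-K specifically to visualize
  all neurons.
* **Sensitization** — the ratio of the first post-incubation capsaicin
  response (pulse 6) to the second pre-incubation response (pulse 4),
  under the 5-pulse / sensitizer / 6th-pulse / high-K protocol. Cells
  whose pulse-4 response is below the floor are excluded: their ratio is
  noise over noise. A cell counts as sensitized when the ratio exceeds
  1.1 — again a package choice, placed well above the ratio noise of
  non-sensitized cells (~1.00 ± a few percent) and well below genuine
  sensitization (~1.4).
* **Temperature matrices** — per-cell $\Delta F/F_0$ rows ordered by
  descending response to the hottest step (ties by cell id; published
  heatmaps do not state their ordering, so it is defined here), plus the
  column-wise mean trace.

The synthetic population gives each cell a transient (2 s linear rise,
20 s exponential decay — fast relative to the 5-min washouts, so
per-stimulus peaks are separable) at every stimulus it responds to,
mutually exclusive category labels, and all cells respond to high-K. In
sensitized cells the 6th-pulse amplitude is exactly the multiplier times
the 4th-pulse amplitude, making the statistic's recovery testable to 1%.

```{r sensitization}
prot <- sensitization_protocol()
pop <- sim_calcium_population(100, frac_caps = 1, sens_multiplier = 1.4,
                              frac_sensitized = 1, protocol = prot,
                              cfg = sim_config(seed = 2, fs = 1))
ratios <- sensitization_ratios(pop$cells, prot)
mean(ratios$sens_ratio)
```

## Expression summaries

`size_factors()` implements the median-of-ratios estimator on the log
scale (per sample, the median over genes with positive counts everywhere
of the log-ratio to the gene's geometric mean); the test suite
cross-checks it against `DESeq2::estimateSizeFactorsForMatrix` to 1e-8.
`marker_relative()` divides each gene's normalized count by the marker's
(ISL1 in the motivating application) in the same sample and averages
within condition; because the ratio forms within a sample, it cancels any
per-sample scale factor, making upstream normalization belt-and-braces —
a property the tests document. `center_scale()` uses the population SD
(denominator $n$); the published figure caption does not say which, and
population SD makes the row-identity checks exact. Constant rows become
zeros and are flagged. Joint size factors are estimated across all
samples at once (rather than per pair of timepoints), matching how a
single normalized matrix is used downstream.

## Noise defaults and what the tests do not show

No noise statistics are published for the recordings this package models;
the generator defaults (e.g. 5 pA for current traces, 0.5 mV for voltage,
0.02 ratio units for calcium) are package choices at the scale a
practitioner would call realistic for the respective modality. Additive
Gaussian noise only; an optional linear drift term is deliberately out of
scope. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated model — clean exponential kinetics, separable
transients, stationary noise — not robustness to every artifact of real
recordings (electrode drift, seal instability, movement, dye bleaching).
Problem sizes used in the validation suite (25-sweep averages at 100 kHz,
200 noisy mechanical trials, 500-cell calcium populations, 1000-gene
count matrices) were chosen to make Monte-Carlo summaries stable at the
tolerances tested.

## Known limitations

* Vendor acquisition formats (ABF/HEKA) are not parsed; traces enter as
  delimited text with a three-line header.
* The RC model is a single compartment; distributed (neurite) capacitance
  is not modeled, matching the somatic recordings the recipe targets.
* Sub-millisecond inactivation components are not resolvable under the
  1 kHz analysis filter and are excluded from the weighted constant by
  design.
* Fura-2 ratios are not calibrated to absolute calcium concentration, and
  no spike inference from calcium is attempted.
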