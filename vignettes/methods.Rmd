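---
title: "Models and methods behind ieplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ieplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieplast)
```

## What the package quantifies

CA1 pyramidal neurons can adjust their intrinsic excitability — how strongly
they fire for a given input current — in response to their own recent spiking.
`ieplast` implements the full quantification pipeline for one such
phenomenon: after a theta-burst firing episode (bursts of ~10 spikes at
100 Hz repeated at 5 Hz, the firing pattern of a place cell crossing its
field), the cell's firing output drops for tens of minutes, its input
resistance falls, its first-spike latency grows, and the magnitude of all
three scales with how many spikes the burst protocol evoked. The effect is
homeostatic (stronger firing, stronger depression) and is consistent with an
upregulation of a slowly inactivating D-type potassium current (Kv1.1,
axon initial segment) rather than the dendritic
hyperpolarization-activated current I~h~.

The package contains three layers:

1. **A synthetic-data generator** — a conductance-based model neuron driven
   by the current-step and theta-burst protocols, with a spike-count-coupled
   plasticity rule, and a place-cell session generator with lap-to-lap
   multiplicative rate drift.
2. **Feature extraction** — the operational definitions of input resistance,
   series resistance, sag ratio, spike threshold, AHP, latency, burst index
   and membrane-potential variance, applied to raw sweeps.
3. **Statistics** — input–output curve normalization, paired and two-sample
   comparisons, stimulation-strength correlations, and the place-cell
   population tests (session thirds, lap-rate correlations, distribution
   center tests).

## The model neuron

The simulator is an exponential integrate-and-fire neuron with two
voltage-gated currents:

$$C_m \dot V = -g_L(V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
  - g_h\, h\,(V - E_h) - g_D\, a\, d\,(V - E_K) + I(t)$$

* $h$ is the I~h~ activation gate: opens on hyperpolarization
  ($V_{1/2} = -82$ mV, slope $-9$ mV, $\tau = 40$ ms), reversal $-30$ mV.
  It produces the depolarizing "sag" on hyperpolarizing steps.
* $a \cdot d$ gates the D-type K⁺ current: a fast activation gate with a
  deliberately shallow voltage dependence ($V_{1/2} = -44$ mV, slope
  $10$ mV, $\tau = 6$ ms) and a slow inactivation gate
  ($V_{1/2} = -72$ mV, slope $-7$ mV, $\tau = 300$ ms). The shallow
  activation leaves a small standing ("window") conductance at subthreshold
  potentials — which is what couples the current to the measured input
  resistance — while its suprathreshold drive grows with depolarization, so
  that an increase in $g_D$ depresses the spike count roughly uniformly
  across the tested step amplitudes. The slow inactivation is what delays
  the first spike.
* A spike is registered when $V$ crosses $+20$ mV; $V$ resets to $-58$ mV
  for a 2.5 ms refractory period. Gates keep evolving through the reset.

Defaults give an input resistance near 50 MΩ, a sag ratio near 0.9, and
8–18 spikes over the 300 ms step range used per cell — the working regime
of anesthetized in vivo recordings from CA1 pyramidal cells.

Integration is forward Euler at `dt = 0.025` ms by default; the gate and
spike nonlinearities are tabulated on a 0.05 mV grid (interpolation error
well below the Euler error). The replicate-level Monte Carlo analyses in
the test-suite and the acceptance script integrate at `dt = 0.05` ms, which
leaves every reported statistic unchanged within its sampling noise while
halving runtime; single-cell examples use the 0.025 ms default.

### Noise model

Three noise sources emulate the variability of in vivo recordings:

* **Fast membrane noise** — diffusive voltage noise with stationary
  standard deviation `noise_sd` (default 1.4 mV), giving spontaneous
  V~m~ variance near 2 mV², in the range reported for anesthetized
  recordings.
* **Trial-to-trial excitability jitter** — a standing-current offset drawn
  per sweep (sd 40 pA). Under anesthesia, cortical and hippocampal state
  fluctuations make the spike count at a fixed step amplitude vary by
  several spikes between repeats; without this term the simulated
  input–output data are far cleaner than any recording, and pooled
  regression comparisons acquire unrealistic power.
* **Between-timepoint drift** — a standing-current offset drawn per testing
  block (sd 12 pA), so that control cells show percent-change scatter
  between timepoints comparable to the experimental control group rather
  than near-zero.

### The plasticity rule

The transfer function from evoked spikes to conductance change is not
measured by any experiment we know of; the package uses the simplest
monotone rule — linear with saturation:

$$g_D \leftarrow g_D\,[1 + \min(\alpha_D n, \mathrm{cap}_D)], \qquad
  g_h \leftarrow g_h\,[1 - \min(\alpha_h n, \mathrm{cap}_h)]$$

with $n$ the number of spikes evoked during the theta-burst stimulation.
Defaults ($\alpha_D = 4/300$ per spike, $\mathrm{cap}_D = 4$;
$\alpha_h = 0.36/300$, $\mathrm{cap}_h = 0.4$) were calibrated once so that
a fully entrained protocol (~300 spikes) yields group effects of the
magnitude observed experimentally (firing −20 to −30%, input resistance
−5 to −10%, latency roughly doubling, sag ratio slightly *increased* via
the I~h~ reduction). The rule is a phenomenological stand-in, not a
mechanistic claim.

Drug conditions are parameter regimes: calcium chelation (BAPTA) sets both
$\alpha$ to zero; NMDAR block (MK-801) leaves the rule untouched; I~h~
block (ZD7288) sets $g_h = 0$; Kv1.1 block (DTX-K) reduces $g_D$ to 30%
and halves $\alpha_D$. Control cells are tested repeatedly without
stimulation.

### Protocol emulation

The testing protocol is fixed to the experimental one: 300 ms steps at
1.5 s intervals, hyperpolarizing amplitudes −300/−250/−200 pA, 10 repeats,
holding −60 mV via a bias current solved from the steady state. The
depolarizing range is adjusted per cell, as in the recordings: the smallest
step is placed where the noise-free cell fires ~8 spikes and the largest
where it fires ~18, with four evenly spaced steps. Starting the range above
rheobase keeps the spike-count floor (zero) away from the tested range;
that floor otherwise distorts the normalized input–output comparison in a
way the original analysis design did not have to contend with.

The theta-burst command is built from EPSC-like difference-of-exponential
waveforms (rise 0.5 ms, decay 3 ms): 10 pulses at 100 Hz per burst, 10
bursts at 5 Hz, 3 series at 15 s intervals — 300 pulses. The EPSC amplitude
is calibrated on the regime's baseline cell (smallest grid amplitude that
entrains ≥ 90% of a burst, plus 20% headroom) and then jittered per cell
(log-normal, 35% CV) to emulate variable entrainment quality across
recordings; this is what spreads evoked spike counts over roughly 100–300
and gives the spike-count/effect-size correlation a usable predictor range.
Because the 15 s inter-series and 1.5 s inter-sweep intervals far exceed
every model time constant, series and sweeps are integrated independently
from the holding steady state.

## Feature definitions

All features follow fixed operational definitions; each is validated
against an independent brute-force oracle in the test-suite.

* **Spike detection**: threshold is the first sample in a rising phase
  where central-difference dV/dt ≥ 10 V/s; the peak is the maximum of the
  following 5 ms. Crossings not followed by a ≥ 20 mV rise are rejected as
  noise (the membrane noise otherwise produces a handful of false
  crossings per sweep at 4 σ).
* **Input resistance**: minimum voltage within 150 ms of step onset minus
  the 50 ms pre-step baseline, divided by the step current; repeats
  averaged per amplitude, cell value = median across the three amplitudes.
* **Sag ratio**: median deflection over the final 50 ms of the step divided
  by the minimum deflection within the first 150 ms, on baseline-subtracted
  voltages — so the measure is invariant to the holding potential, and
  "less sag" moves the ratio toward 1.
* **Series resistance**: a single exponential fitted between 5 and 15 ms
  after onset, extrapolated back to onset; the extrapolated drop is
  regressed on the injected current. The fit runs on the repeat-averaged
  trace per amplitude: with correlated membrane noise, single-trace fits
  over a 10 ms window are unstable under the back-extrapolation, while the
  average of 10 repeats (which is also what example traces in published
  figures show) gives a stable estimate. The profiled least-squares fit
  constrains the time constant to 2–200 ms.
* **AP threshold**: median over depolarizing sweeps of the first spike's
  threshold voltage.
* **AHP**: minimum voltage within 50 ms after a spike's threshold; spikes
  whose window contains the next spike's threshold or the step end are
  excluded; eligible spikes are averaged across sweeps.
* **Latency**: time from step onset to the first threshold on the maximal
  steps, averaged over repeats.
* **Burst index**: a spike is "in a burst" if it participates in any
  inter-spike interval < 10 ms; per-sweep fractions are averaged per
  amplitude (a pooled-spikes mode is available behind a switch), and the
  cell value is the maximum over amplitudes whose mean count ≥ 5.
* **V~m~ variance**: variance in non-overlapping 5 s segments of
  spontaneous recording (spikes blanked ± 5 ms), median across segments.
* **QC**: resting V~m~ < −55 mV, R~s~ < 100 MΩ, spike amplitude > 40 mV,
  all strict.

Where the aggregation order was ambiguous (mean over repeats before or
after the median over amplitudes), the package averages repeats first and
takes the median across amplitudes, and applies the same order to the sag
ratio; both choices are deterministic and documented here rather than
guessed silently.

## Input–output statistics

Spike counts per amplitude are normalized per cell by
$(X - \mathrm{minPre}) / (\mathrm{maxPre} - \mathrm{minPre})$, where the
extremes are the pre-stimulation means at the smallest and largest step;
the current axis is mapped linearly to [0, 1] per cell. Pooled straight
lines are fitted per timepoint, slope equality is tested by the
current-by-timepoint interaction of the full linear model, and intercept
equality by the timepoint term of the common-slope model (the usual
ANCOVA decomposition). Group statistics are paired t-tests within groups
and two-tailed Welch t-tests between groups on percent changes; the
stimulation-strength relation is ordinary least squares of per-cell change
on evoked spike count. No multiple-testing correction is applied, matching
the original analysis; `p.adjust` can be applied downstream by users who
want it.

## Place-cell sessions

The virtual track is traversed back and forth at constant speed (200 cm,
15 cm/s, 30 laps per direction by default; a ~13 min session). The firing
rate is a truncated Gaussian bump (peak 8 Hz above baseline, sd =
width/3, support = centre ± width/2) plus a 1.6 Hz out-of-field baseline.
Per lap, the baseline is multiplied by `drift_per_lap` and the bump by
`in_field_gain_per_lap`; a drift of 0.985 over 30 laps reproduces the
start-to-end decline seen in the out-of-field rates of place cells in a
novel environment, and a gain slightly above 1 the in-field increase.
Spikes are generated per (lap, bin) as Poisson counts on a 2 cm grid —
with constant speed this is exactly an inhomogeneous Poisson process with
piecewise-constant rate — and spike times are placed uniformly within each
bin's dwell interval. For population Monte Carlo runs the analysis can
work from the generator-native count matrices directly
(`use_counts = TRUE`); a test verifies that re-binning the spike times
recovers the same statistics.

Analysis: laps are segmented at position turnarounds and each direction is
analyzed independently; rate maps are spikes over occupancy per 2 cm bin;
the field is the largest contiguous run of bins ≥ 20% of the peak rate
containing the peak bin; stability is the mean of all pairwise Pearson
correlations between per-lap maps (each map Gaussian-smoothed with a 2-bin
sd first — at behavioral firing rates unsmoothed single-lap maps are
Poisson-dominated and no cell would reach the conventional 0.1 inclusion
cutoff); spatial information is the Skaggs bits-per-spike measure; cells
enter the population analysis when stability and spatial information both
exceed 0.1. Session thirds are defined by time (boundary laps join the
earlier third) and compared by one-way repeated-measures ANOVA; the
lap-rate correlation distribution's center is tested against zero by a
one-tailed t-test when Shapiro–Wilk does not reject normality at 0.05,
otherwise by a sign test.

One deliberate choice: the direction of the one-tailed center test is fixed
by the hypothesis under test (out-of-field: decrease; in-field: increase)
rather than chosen from the sample mean's sign. Choosing the tail from the
data doubles the null false-positive rate to ~10%; with a fixed direction
the test is calibrated at its nominal 5% level, which the test-suite checks
over 1000 null populations.

## What the generator does and does not emulate

The synthetic data reproduce the statistical structure the analysis
assumes: step-and-burst protocols, sag and delayed firing, spike-count-
coupled depression, heterogeneous cells (log-normal 10% CV on conductances
and capacitance), trial and block excitability fluctuations, and drifting
place-cell sessions. They do not emulate electrode properties (series
resistance enters only through analytic validation fixtures), synaptic
bombardment structure (noise is diffusive, not conductance-based),
dendritic processing, theta phase, or behavioral variability in running
speed and occupancy. Passing the parameter-recovery tests therefore shows
that the pipeline detects the directional pattern it was built to detect
under realistic noise — not that the conductance model is a validated
biophysical account of the phenomenon.

## Problem sizes and reproducibility

The test-suite and `scripts/acceptance.R` use: 100 replicate cohorts
(stimulated n = 16 vs control n = 11) for directional parameter recovery;
30–40 replicates per pharmacology regime; 1000 driftless populations of 60
cells for the type-I calibration and 200 drifting populations of 171 cells
for detection power; and ≥ 100 randomized sweeps for oracle equivalence.
Every random quantity derives from a single master seed through a
deterministic per-cell/per-replicate seed derivation, so all outputs are
bit-reproducible given the seed.
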