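---
title: "Closed-loop alpha feedback: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop alpha feedback: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphaloop)
```

`alphaloop` models a closed-loop analog neurostimulation experiment: cortical
alpha (8–15 Hz) local field potential (LFP) oscillations are band-pass
filtered by an analog circuit, delayed by the digital recording chain, and
fed back to the brain as transcranial current, so that stimulation arrives
nearly in phase with the ongoing rhythm. The package contains (i) the filter
and loop model, (ii) a per-sample simulator of the loop acting on a
stochastic alpha oscillator, (iii) statistical generators of synthetic
multi-array LFP sessions with known injected effects, and (iv) the complete
offline analysis pipeline with resampling inference. This vignette documents
the models, the estimators, and every design decision that was genuinely
open.

## 1. The filter and the loop phase budget

The feedback element is a single-stage second-order multiple-feedback (MFB)
active band-pass filter with equal capacitors. Its transfer function in the
standard form is

$$A(s) \;=\; \frac{-\,G\,\frac{\omega_0}{Q}\,s}
{s^2 + \frac{\omega_0}{Q}\,s + \omega_0^2},
\qquad
\omega_0^2 = \frac{R_1+R_3}{R_1R_2R_3C^2},\quad
Q = \frac{\omega_0 R_2 C}{2},\quad
G = \frac{R_2}{2R_1},$$

which `design_mfb()` inverts for component values; realizability requires
$2Q^2 > G$. The topology is naturally inverting, so the phase at exactly
$f_0$ is 180°. The canonical design is $f_0 = 12$ Hz, $Q = 1.5$: an 8 Hz
−3 dB bandwidth spanning 8–16 Hz, slightly wider than the 8–15 Hz alpha
band, with arithmetic centering (12 is named as the center frequency, and
$f_0/Q$ reproduces the stated band edges).

```{r}
spec <- design_mfb(12, 1.5)
frequency_response(spec, c(8, 11.6, 12, 16))
```

The digital recording/conversion chain contributes a pure delay, 42 ms by
default — 175° at 11.6 Hz. `loop_phase()` reports the unwrapped total,
filter inversion included, increasing with frequency:

```{r}
loop_phase(spec, loop_config(), c(11.6, 12))
```

A note on an internal inconsistency of the phase budget this models: a
second-order MFB stage plus a pure 42 ms delay gives ≈361° at 12 Hz, not
372°; and 42 ms is 181.4° at 12 Hz, not 175°. The constraint treated as
authoritative here is "360° at 11.6 Hz", which the model satisfies within
1.5°. A total of 372° at 12 Hz is not reproducible from any pure
second-order + pure-delay model and is flagged as such rather than fitted.

**Discretization.** `apply_filter()` realizes the stage as a biquad via the
bilinear transform with frequency pre-warping at $f_0$ — the standard choice
at audio-like rates, preserving the center-frequency phase exactly. At
1000 Hz sampling the discrete response matches the analytic one to well
under 1% in magnitude and 2° in phase over 5–30 Hz. The digital delay is
rounded to whole samples; the command is hard-clipped at
±`command_limit` (0.5 V, i.e. ±1 mA through the 2 mA/V stimulator gain).
Default simulations are titrated to stay mostly below the limit, matching
the "no clipping" operating regime of the physical system.

## 2. The simulated plant and the interference mechanism

The "brain" is a damped harmonic oscillator — an AR(2) process with natural
frequency 11 Hz — driven by white noise, on top of a 1/f background
(`plant_config()`, `simulate_plant()`). Two parameters deserve comment:

* **Damping 0.012.** The amplitude decay constant is
  $1/(\zeta\omega_n) \approx 1.2$ s, chosen so that stimulation-built
  amplitude largely dissipates within about one second of offset — the
  persistence scale of the post-stimulation effects being emulated.
* **Drive coupling.** Stimulation current enters the *velocity* equation of
  the oscillator: the command is passed through a differentiator normalized
  to unit gain (and a +90° lead) at $f_n$ before being added to the state
  update. This is the point where a modelling decision was unavoidable. A
  force acting on the *position* response of a resonator lags it by 90° at
  resonance, so feedback arriving in phase with the recorded potential
  would not pump energy into the rhythm — contradicting the premise that
  stimulating at oscillatory peaks constructively interferes. Coupling the
  drive to the velocity state makes "command in phase with the recorded
  oscillation" equivalent to "force in phase with velocity", which is
  exactly the energy-pumping (negative-damping) regime. With this choice a
  net loop phase near 0° (mod 360°) amplifies the rhythm and an extra 180°
  (command polarity inversion, `loop_config(polarity = -1)`) suppresses it,
  as the closed-loop acceptance property requires. Whether the real effect
  is additive drive or excitability modulation cannot be resolved from the
  data being emulated; the simulator implements additive drive only.

The loop is simulated per sample in compiled code (`run_session()`): plant
output → preamp gain (1 mV/µV, the titratable analog-output gain) → biquad →
42-sample delay line → polarity → hard clip → stimulator transconductance →
coupling → plant drive. `loop_gain()` gives the small-signal resonant loop
gain; the default coupling (0.0296 µV/mA) sets it to 0.5, safely inside the
stability margin, and `calibrate_coupling()` retargets it. The
constructive/destructive acceptance runs use a gain of 0.65 and 20-trial
sessions, so that stimulation-built alpha amplitude decays measurably into
the post-offset analysis window.

Open/Brain controls reproduce the two open-loop conditions: a fixed 11.5 Hz
sinusoid, and an 8–16 Hz-filtered plant trace simulated with a different
seed ("a previous day's recording"), both clipped identically.

## 3. The synthetic session generator

`generate_session()` builds sessions with exactly the structure the analysis
assumes, with known ground truth. Key choices, all in microvolts and at
1000 Hz by default:

* **Alpha rhythm**: narrow-band (8–15 Hz, 4th-order Butterworth edges)
  filtered Gaussian noise, 200 µV RMS per channel — effects injected on it
  are broad-band within alpha, not a narrow spectral line. Per array, 30%
  of the rhythm's power is a shared component and 70% is electrode-private
  (`alpha_share`): field coherence falls off over millimetres, and most
  electrode pairs on a multi-millimetre grid are far apart. Injected
  effects scale shared and private parts alike, so array specificity is
  preserved.
* **Background**: 1/f noise (first-order pole/zero cascade approximation,
  100 µV RMS) plus 20 µV white sensor noise, per channel. In the 8–15 Hz
  band the background carries only ~2–3% of the rhythm's power, so a
  multiplicative effect of g on the rhythm appears in measured band power
  as ≈ g with a dilution bias of about −0.01 dB at 0.5 dB.
* **Saturation artifact**: single-ended channels are clamped to a ±5 mV
  rail while current flows and recover exponentially (τ = 0.1 s in vivo);
  the bipolar controller trace is clean throughout, reflecting its
  common-mode rejection. Offsets are *marked* at desaturation: in vivo
  0.3 s after current stops (marked durations uniform on 7.74–10.74 s); in
  vitro the amplifier settles far more slowly, so marked durations are
  drawn uniform on 12–21 s (median 16.5 s). The 20 s in vitro rejection
  limit therefore retains most trials while the 11 s in vivo limit rejects
  all of them.
* **Effects** (`effect_spec()`): a condition/array/band-targeted
  multiplicative power change `10^(effect_db/10)`, applied as an amplitude
  envelope with 50 ms cosine ramps, default onset at the marked offset and
  default duration 1 s. The parameter-recovery experiments inject a 1.5 s
  plateau: the 8 Hz wavelet has ±0.5 s of temporal support, so a plateau
  must extend ≥0.5 s beyond the 0.5–1.0 s analysis window for the window
  mean to estimate the plateau level rather than an edge-smeared mixture.
  The estimand of those experiments is the plateau level.

`generate_saline_session()` produces the in vitro control: identical
container and schedule, no oscillatory component at all.

## 4. The analysis pipeline and its estimators

`run_pipeline()` executes, per condition (pooling epochs across sessions):

1. **Prep**: epoch −5..+5 s around marked onsets and offsets (half-open
   windows at sample resolution, so a 10 s epoch is exactly `10*fs`
   samples and the alignment sample is not double-counted); reject trials
   whose marked duration exceeds 11 s (in vivo) / 20 s (in vitro); drop
   the controller pair and dead channels. No artifact correction of any
   kind is applied; the run log records `"rejection only"`.
2. **TFR**: complex Morlet convolution, 5–30 Hz in 1 Hz steps with cycle
   counts matched 5–30 — a constant envelope SD of $1/2\pi$ s across the
   family. Wavelets are zero-mean and unit-energy (`sum |w|² = 1`), under
   which white-noise power is flat across frequencies. Onset and offset
   epochs are transformed *separately*, the stimulation halves are dropped
   in the power domain, and the remaining halves concatenated — so the
   convolution near the splice is supported by real data and no
   discontinuity enters any wavelet. Samples within 4 envelope SDs of an
   outer epoch edge are flagged invalid (NA) and excluded from all medians;
   with the default family this invalidates the outer 0.64 s of the
   concatenated epoch, leaving the −5..−1 s baseline and 0.5–1 s window
   usable at every frequency. The high-gamma family (80–200 Hz, cycles =
   f/2) is a documented extrapolation: the stated low-frequency family
   stops at 30 Hz, and no construction for 80–200 Hz is specified, so
   high-gamma results rest on this package's convention and are checked by
   properties only.
3. **Normalization** (`normalize_median_db()`): per channel and frequency,
   (a) each epoch divided by its own median over valid times, (b) the
   across-epoch median at each timepoint, (c) division by the grand median
   of the −5..−1 s baseline, (d) `10*log10`. The epoch-median step makes
   the estimator robust to slow per-trial amplitude drifts, and because the
   per-epoch factor is common to window and baseline it cancels almost
   exactly in the final ratio.
4. **Summaries**: arithmetic band means over the inclusive discrete
   frequency sets (alpha 8–15, beta 15–30, high gamma 80–200 Hz — 15 Hz
   deliberately belongs to both alpha and beta, as the stated ranges read),
   then the time mean over the 0.5–1.0 s post-offset window (0.5–1.5 s
   supported as the wider alternative).
5. **Statistics**: trial bootstrap against zero (percentile CI; both
   one-sided masses reported; headline p = 2·min(mass above, mass below)
   capped at 1, since a one-sided "mass above zero" rule is
   direction-ambiguous); condition-label permutation with the two-sided
   `|null| ≥ |observed|` rule, literally as a fraction with no +1
   correction; electrode-level array-membership permutation (the unit of
   exchange is the electrode); BH-FDR within each band's family of three
   condition pairs (and likewise within the bootstrap and array families —
   within-band only, not across bands). Exhaustive enumeration replaces
   Monte-Carlo automatically when the permutation space is small. Every
   result records its seed; identical seeds give identical results.

**Channel aggregation.** Whether band power should be averaged across
electrodes in dB or in linear units before the trial-level summary is
genuinely underdetermined. This package averages step-1-normalized power
across electrodes linearly *before* the across-epoch median for the
condition-level statistics — the across-epoch median must be recomputed
inside every bootstrap/permutation draw, and doing that per electrode is
computationally prohibitive — while the array permutation test uses full
per-electrode dB summaries (steps b–d per electrode), matching its
electrode-level unit of exchange. On 100-trial null sessions the two
aggregation orders agree to well within the between-seed variability of the
estimator (property-tested at 0.2 dB).

**Resampling recomputes normalization.** Steps (b)–(d) are recomputed
within every draw; only step (a) is frozen per trial. The grand baseline
median may be evaluated on a strided baseline grid (`baseline_stride`);
observed estimates and all draws always share the same grid, and because
the across-epoch median trace is smooth on the wavelet timescale, a stride
of 4 changes summaries by far less than 0.01 dB. Resampling-heavy runs use
stride 4.

**PL/NPL decomposition.** Phase-locked power is the Morlet power of the
across-trial median voltage (an evoked potential robust to outliers);
non-phase-locked power is that of the trials after subtracting the evoked
waveform, per condition. The PL stream has a single pseudo-trial, so
trial-resampling statistics are computed for the total and NPL streams
only.

## 5. What the synthetic data do and do not establish

The generators emulate: the sampling rate, array geometry (10×10 grid,
corners removed, 96 electrodes), the bipolar controller pair and its
artifact immunity, dead channels, trial schedules with manual-timing
jitter, amplifier saturation and slow in vitro desaturation, 1/f
background, a broad-band alpha rhythm with partial spatial coherence, and
multiplicative post-offset band-power effects of the ~0.1–0.5 dB order.
They do not emulate: electrode impedance structure, cardiorespiratory or
movement artifact, non-stationary alpha peak drift, cross-frequency
coupling, or any tissue-level stimulation physics beyond the additive-drive
plant. Passing recovery tests therefore demonstrates that the *pipeline* is
unbiased and correctly calibrated for effects of the kind injected — not
that real recordings satisfy these assumptions.

One calibration property deserves emphasis. A saline (null) session
analyzed with the full battery runs 18 tests in six BH families of three;
for perfectly calibrated tests the chance that *all* of them clear 0.05 is
about $0.95^6 \approx 0.74$ per session. Requiring near-universal
all-clear across many null sessions is thus not achievable by any
correctly calibrated analysis — it would demand family-wise control across
the entire battery, which the within-band correction deliberately does not
impose. The package's saline tests verify instead that per-test
uncorrected rejection rates are nominal, and report the all-clear fraction
for what it is.

## 6. Problem sizes used by the test suite

Unit and acceptance tests generate all data in code, at sizes chosen to
probe each property with adequate statistical resolution: circuit checks
are analytic; closed-loop interference uses 10 matched-seed triplets of
20-trial sessions at 1000 Hz on a 4-electrode map; parameter recovery uses
100-trial, two-array sessions (8 electrodes per array) at 250 Hz sampling
with the alpha-band wavelet family — alpha content is fully preserved at
that rate — across 20 seeds per effect level; saline nulls use 3×8-trial
sessions at 500 Hz (the high-gamma family needs Nyquist above 200 Hz) with
500-draw resampling, the scale at which permutation p-values resolve to
0.002. The full-size defaults (96-electrode arrays, 1000 Hz, 5000 draws)
remain the package defaults throughout.

## 7. Known limitations

* The plant is linear; clipping is the only nonlinearity in the loop.
  Entrainment phenomena (Arnold tongues, phase walk-through) are out of
  scope.
* The high-gamma wavelet family is a convention, not a reconstruction.
* The bootstrap CI is percentile-based; at very small trial counts it is
  mildly anticonservative, which matters only below ~10 trials.
* `read_session()`/`write_session()` define this package's own plain
  container (JSON + CSV + flat binary); no vendor acquisition formats are
  read.
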