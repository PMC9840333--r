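---
title: "Methods: chirp-evoked EEG entrainment and TMS metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chirp-evoked EEG entrainment and TMS metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Auditory chirp paradigms probe how well cortical circuits follow a driven
rhythm. A 1000 Hz tone is amplitude-modulated by a sinusoid whose frequency
sweeps linearly from 0 to 120 Hz over 2000 ms; the stimulus is presented 160
times with inter-stimulus intervals jittered uniformly in 1500–2500 ms.
The EEG response contains (a) a low-frequency onset response in the first
~500 ms and (b) an *entrainment* response whose instantaneous frequency
tracks the AM sweep — a diagonal ridge in the time–frequency plane. Because
the generators of high-frequency entrainment are thought to be GABAergic
interneuron networks, the strength and phase stability of that ridge is used
as a non-invasive marker of inhibitory function, compared across groups
(e.g., mTORC1-pathway mutation carriers vs. controls). A companion TMS arm
quantifies intracortical inhibition/facilitation from EMG responses.

`chirpent` implements the full analysis chain plus a synthetic-data module,
so that every stage is testable without any patient recording.

## Analysis model

**Preprocessing.** Channels × samples recordings (µV, 1000 Hz) are
zero-phase filtered to 0.5–150 Hz with a 60 Hz notch; channels with sample
SD outside [2, 120] µV are dropped (flat or saturated); data are cut into
half-open epochs `[-1, 3.5)` s around stimulus onsets (exactly 4500 samples
at 1000 Hz); epochs with any sample strictly beyond ±200 µV are removed;
four ROI averages are formed (frontal F3/F1/Fz/F2/F4, central
C1/Cz/C2/FC1/FCz/FC2, parietal P3/P1/Pz/P2/P4, occipital
O1/Oz/O2/PO3/POz/PO4).

The published SD bounds are printed in millivolts; scalp EEG never spans
millivolt standard deviations, so the bounds are read in microvolts. The
bounds are evaluated on the filtered continuous recording, before epoching.
The epoch-amplitude rule is applied strictly (`> 200`): a sample exactly at
200 µV is retained. The upstream tag-then-inspect manual pass is replaced by
tag-and-remove, since visual inspection is not reproducible.

**Filter realization.** No IIR filter-design library is available in the
target environment, so the filter is applied in the frequency domain with a
purely real transfer function equal to the *squared magnitude* of a
4th-order Butterworth bandpass cascaded with a biquad notch (Q = 30) — i.e.
exactly the magnitude response that forward–backward (`filtfilt`)
application of those filters would produce, with zero phase by construction.
Reflection padding (5 s) suppresses wrap-around transients. The testable
contracts hold: ≥ 20 dB attenuation at 60 Hz, < 1 dB passband ripple at
10 Hz, DC removal, linearity, and bit-reproducibility.

**Time–frequency decomposition.** Complex Morlet wavelets, unit L2 energy,
on a 2–120 Hz grid (1 Hz steps by default). The cycle rule is
`n_cycles(f) = max(3, f/2)` — 3 cycles at low frequencies growing to 60 at
120 Hz — mirroring the expanding-cycles default of the common EEG toolboxes;
the kernel is truncated at ±3 σ_t. Cells closer than half a kernel to an
epoch edge are flagged invalid and excluded from every summary. No padding
is used.

**ERSP** is divisive on trial-averaged power,
`10·log10(P(f,t) / B(f))`, with the baseline `B(f)` the mean power over
−800 to −200 ms. At the lowest frequencies part of that window is
edge-invalid; the baseline then uses only the valid cells (still ≥ 80 ms of
data at 2 Hz). A frequency with zero baseline power is an error, not a
silent `-Inf`. **ITC** is the modulus of the trial-mean unit phasor;
cells with a vanishing coefficient are excluded trial-wise. Under no
locking, ITC has expectation `sqrt(pi/(4n))` — 0.070 at n = 160 — which the
tests use as an analytic null.

**Masks and band extraction.** The whole-sample mean *frontal* ITC map
defines two masks: cells with ITC ≥ 0.13 inside 0–500 ms (onset) and inside
750–2250 ms (entrainment). The threshold is inclusive (the figure-caption
convention wins over the methods-text `>`), and the entrainment window ends
at 2250 ms (the methods-text value wins over the caption's 2500 ms); both
are arguments, so either variant can be reproduced. One shared mask pair is
applied to all subjects and all four ROIs. Band summaries are within-mask
means over closed frequency intervals: theta 3–8, alpha 8–14, beta 14–17 Hz
on the onset mask; low gamma 30–55 and high gamma 65–100 Hz on the
entrainment mask. The printed onset bands share boundary frequencies, and
the closed intervals reproduce that overlap deliberately. An empty
mask-band intersection yields `NA` with a warning, never a silent zero.

A consequence worth knowing: the mask threshold competes with the ITC noise
floor. At n trials the floor is `sqrt(pi/(4n))` — 0.198 at n = 20, above
the 0.13 threshold — so masks built from low-trial maps select almost the
whole window. Masks should be built from high-trial-count (or
many-subject-averaged) maps; `simulate_study()` accepts a precomputed mask
pair for exactly this reason.

**Group statistics.** Per (ROI, band, measure) outcome: Shapiro–Wilk per
group, Levene (ANOVA on absolute deviations from the group mean; a
Brown–Forsythe median option exists), one-way fixed-effects ANOVA
(significance at 0.05), and pairwise post-hocs on the studentized range:
Tukey HSD when Levene p ≥ 0.05, Games–Howell (unpooled variances, Welch
degrees of freedom) otherwise. The routing rule is this package's decision;
the source analysis lists both tests without stating when each was used.
Welch ANOVA is deliberately *not* substituted under heteroscedasticity —
the omnibus test stays classical, and heterogeneity is handled only at the
post-hoc stage. No multiplicity correction is applied across outcomes; the
result object reports how many outcomes were tested so users can correct
post hoc.

**TMS metrics.** Peak-to-peak MEP amplitude inside a 15–60 ms window after
the (test) pulse — a typical FDI latency range, stated in the output
because the source protocol does not fix one. SICI/ICF/SICF are
mean-conditioned over mean-baseline ratios (< 1 inhibition, > 1
facilitation); LICI is the per-trial second/first MEP ratio averaged over
trials, with a noise-floor exclusion (first MEP below 3× the peak-to-peak
excursion of an equal-length pre-pulse segment — comparing extreme ranges
with extreme ranges, not with an SD). The cortical silent period is
detected on the 5 ms-smoothed rectified EMG as the time from pulse to the
first ≥ 10 ms-sustained return above 50% of the pre-pulse rectified mean;
absence of a pre-pulse contraction is an error (a CSP is undefined without
contraction), and absence of silence returns the MEP decay time flagged
short. Input/output curves are mean ± SD peak-to-peak per intensity
(100–150% rMT, 10% steps). rMT estimation itself is out of scope: trials
arrive labelled in %rMT.

## The synthetic world

`simulate_eeg_session()` generates, per channel, 1/f background noise
(spectral shaping of white Gaussian noise; slope 1, RMS 10 µV by default)
plus, per trial: a Hann-windowed 5 Hz onset burst (0–500 ms) and an
entrained sinusoid whose instantaneous frequency follows the stimulus AM
sweep over 0–2 s with 100 ms on/off ramps. Both components share a
per-trial phase offset drawn von Mises around 0 with concentration κ
(Best–Fisher sampler; κ = 0 is the exact uniform null, large κ near-perfect
locking). Components are weighted frontally (frontal 1.0, central 0.7,
parietal 0.5, occipital 0.3, fillers 0.4) — the study reports only "greater
phase-locking over the frontal region", so the topography is a modelling
choice, not a reproduced fact. Blink-like artifacts are 300 ms, 350 µV
raised-cosine transients (< 4 Hz content) with frontal topography, at a
configurable per-minute rate, giving the ±200 µV rejection stage true
positives. Bad channels are rendered flat (SD « 2 µV) or saturated
(SD > 120 µV). Identical parameters and seed give bit-identical output.

The neural entrained component is modelled at the AM *envelope* frequency,
not the 1000 Hz acoustic carrier: the following response tracks the
envelope, and the analysis band is 0–120 Hz.

Group defaults encode the contrast the analysis targets: carriers get
stronger, more phase-locked entrainment (gain 5 µV, κ = 2.2) than controls
(gain 4 µV, κ = 1.1). For the acceptance scenario "a true within-mask
low-gamma ITC difference of ≈ 0.1", gains are held equal (4 µV) and only the
locking is raised, κ = 1.1 → 1.7 — the value at which the measured
within-mask difference is 0.10 (calibrated once on the desk-scale
configuration, as the scenario itself prescribes, and frozen).
`simulate_study()` adds between-subject lognormal jitter (CV 15% on κ, 10%
on gains) — a realism choice fixed once; the cohort's true between-subject
spread is unknown.

What a green test does *not* establish: the generator has no 1/f-varying
topographic covariance, no alpha rhythm, no non-stationary artifacts, no
volume-conduction mixing, and the ICA stage of real preprocessing is not
modelled (it depends on visual inspection). Parameter recovery on this
world validates the estimator chain, not the biology.

A physical subtlety the tests exposed: a strong linear chirp leaks
deterministic energy far off its ridge (polynomial sidelobe pedestal, not
the Gaussian falloff of a stationary tone). Off-ridge cells where that
pedestal is comparable to the noise are *partially* phase-locked, enter the
0.13 mask, and dilute within-mask ITC. The ITC-saturation acceptance run
therefore needs a gain-to-noise ratio of order 10³ ("well above noise")
for every masked cell to be pedestal-dominated; at moderate SNR the
within-mask mean honestly sits near 0.7–0.8 even under perfect locking.

EMG trials are built from a biphasic unit-peak-to-peak MEP template at
22 ms latency with small lognormal amplitude jitter; paired protocols place
the conditioning and test pulse at the protocol's ISI (2/4/10/15/3/100/220
ms); CSP trials embed tonic band-limited contraction, an MEP, then silence
ending exactly `programmed_csp_ms` after the pulse; input/output trials
scale the MEP linearly with intensity. Fifteen trials per block by default.

## Numerical choices and degenerate inputs

* Epoch windows are half-open `[tmin, tmax)`; 4.5 s at 1000 Hz is exactly
  4500 samples, avoiding off-by-one disputes.
* dB convention: `10·log10` of a power ratio (amplitude ×2 → +6.02 dB).
* FFT lengths are 5-smooth (2^a·3^b·5^c), not next-power-of-two; this
  halves some transforms with no accuracy cost.
* ITC requires ≥ 2 trials; single-trial ITC is rejected, not returned as 1.
* All-channel rejection, zero surviving epochs, a ROI with no surviving
  electrodes, a frequency with zero baseline power: all are errors with
  messages naming the offender, never silent degradation.
* Every generator is a pure function of (parameters, seed); seeds are
  save/restored so library calls never disturb the caller's RNG stream.

## Scale of the shipped tests

The acceptance suite runs the full chain end to end but at desk scale:
single frontal channels, reduced frequency grids, 40-trial sessions for the
100-replicate group-recovery study (its mask pair is built once from
160-trial calibration sessions, mirroring the single shared mask pair of a
real study), and subject-level resampling for the 2000-replicate type-I
calibration. The physics checked — null ITC level, ridge tracking,
dB arithmetic, mask nesting, ratio recovery — does not depend on the
omitted channels or grid rows; run-time does.

## Known limitations

* No EDF import/export (no EDF library in the supported environment); the
  documented container is flat little-endian float32 + JSON sidecar.
* No ICA artifact rejection, channel interpolation, or re-referencing.
* No cluster-based permutation statistics, mixed models, or covariate
  adjustment.
* rMT hunting and coil localization are out of scope for the TMS arm.
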