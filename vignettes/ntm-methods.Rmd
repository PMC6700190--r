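---
title: "Normalized template matching: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized template matching: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntmdetect)
```

## The detection problem

Extracellular spike detection conventionally thresholds the band-passed
voltage at a fixed multiple of the noise SD (usually 3, in practice
2.8--3.2) and enforces a short shadow (dead-time) period -- 0.66 ms here --
after every accepted crossing so one action potential is not counted
several times. Two failure modes follow directly. Spikes whose amplitude
sits near the threshold are lost outright (sub-threshold misses), and
during dense population firing the shadow clock triggered by *other*
spikes, multi-unit background, or near-threshold noise censors legitimate
spikes (shadowed misses). Both losses concentrate exactly where the
science is: in the stimulus-evoked response window of strongly driven
cortical populations, which biases evoked rates downward and flattens
tuning curves.

`ntmdetect` implements a two-round remedy. Round one is the standard
fixed-threshold pipeline; its only job is to produce mean spike waveforms
("templates") of candidate single units. Round two re-detects spikes by
*waveform similarity* to each template rather than by amplitude.

## The sliding statistic

Let $\mu_i$ be the template of unit $i$: the per-channel mean of its
aligned clips, concatenated channel-major into one row vector of length
$L \cdot N$ ($L = \mathrm{round}(f_s k)$ samples, $k = 1.5$ ms split
0.5 ms before / 1.0 ms after the negative peak; $N = 4$ channels for a
tetrode). For every start sample $t$, $V(t)$ is the same-shape
concatenation of $L$-sample windows of the recording (the window slides
through time, not channel). The sliding cross-correlation is the dot
product

$$C_i(t) = V(t) \cdot \mu_i^{\mathsf T}
  = \lVert V(t)\rVert\,\lVert\mu_i\rVert\,\cos\theta ,$$

and normalized template matching (NTM) uses the scaled form

$$S_i(t) = \frac{C_i(t)}{\lVert V(t)\rVert\,\lVert\mu_i\rVert}
  = \cos\theta ,$$

a sliding cosine similarity: bounded in $[-1, 1]$, invariant to
multiplicative rescaling of the voltage, and independent of the local
signal energy that makes $C_i(t)$ fire on any large event. The
unnormalized variant (TM) is retained so the two methods differ *only* in
the normalization. Windows with $\lVert V(t)\rVert = 0$ are defined as 0.

Both statistics assume the spike shape is stable enough that a mean
waveform is meaningful (gradual electrode drift violates this), and that
detection may key on the negative-going deflection.

## Data-driven thresholds

Each template gets its own detection threshold $\alpha_i$, chosen from the
first-round clips rather than from the noise floor. Every clip $E_t$ is
scored by its cosine similarity $S_{i,t}$ to $\mu_i$; clips assigned to
unit $i$ form the target class and all remaining clips (other units,
multi-unit, noise crossings) the other class. Scanning candidate
thresholds over the observed values, with $TP$ the fraction of target
similarities $\ge \alpha$ and $CR$ the fraction of other similarities
$< \alpha$, $\alpha_i$ maximizes $(TP + CR)/2$, ties resolved toward the
largest candidate. The argmax is piecewise-constant between observed
values, so the observed-values grid loses nothing. When no non-target
clips exist at all -- e.g. a noise-free single-unit recording --
$\alpha_i$ falls back to just below the weakest target similarity
($\min S_{i,t} - 10^{-6}$), so every training clip remains detectable.

Detection then scans $S_i(t)$: the statement "every sample with
$S_i(t) \ge \alpha_i$ is a spike" would fire on each sample of a
supra-threshold bump, so within each contiguous supra-threshold epoch the
sample of maximal similarity becomes the single event (earliest sample on
exact ties), and the 0.66 ms shadow clock applies per template.
Detections from *different* templates closer than 0.5 ms are merged to the
higher-similarity one; for TM the arbitration still compares cosines,
which are comparable across templates where raw dot products are not.
Event timestamps use the alignment-point convention (window start + clip
pre-window), making first-round, second-round and ground-truth tables
directly comparable.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `threshold_sd` | 3.0 | noise SDs | first-round voltage threshold |
| `shadow_s` | 0.00066 | s | dead time after any accepted event |
| `clip_pre_s` / `clip_post_s` | 0.0005 / 0.001 | s | clip window around the negative peak |
| `bandpass` | 300--8000 | Hz | spike band (4th-order zero-phase Butterworth) |
| `fs` | 31250 | Hz | sampling rate the defaults are derived for |
| `reject_sim` | 0.7 | -- | cosine floor of the clustering stand-in |
| `merge_s` | 0.0005 | s | cross-template arbitration window |
| quality gate | 0.5% / 30% | -- | refractory-violation and missing-spike cut-offs |

Preprocessing applies common average referencing before band-pass
filtering; referencing is idempotent and linear, so the order matters
little for Gaussian-like shared noise, and fixing CAR first keeps the
noise estimate tied to the filtered, referenced trace the detector
actually sees. Tetrode pads are selected by the raw fourth central moment
$k_c = E[(v_c - E v_c)^4]$ of each candidate channel. This printed form is
deliberately *not* normalized by $\sigma^4$, so it grows with both
peakedness and scale; `channel_kurtosis(..., normalized = TRUE)` provides
the scale-free variant for users who want it.

## Single-unit quality metrics

Candidate templates must satisfy two gates before the second round:
fewer than 0.5% of inter-spike intervals below 1.5 ms, and fewer than 30%
of spikes estimated missing below the voltage threshold. The missing
fraction fits a Gaussian to the detected negative-peak amplitudes by
*truncated* maximum likelihood -- detected amplitudes are censored at the
threshold by construction, so a naive moment fit is biased toward zero
missing; the moment fit remains available (`method = "moment"`) and is
the fallback when the MLE does not converge. Cluster compactness uses the
Mahalanobis distance after projecting clips onto the three leading
principal directions per channel (12 features on a tetrode), since the
full 188-dimensional covariance is singular for any realistic cluster
size.

Clustering itself is out of scope: the package ships a deliberately
simple stand-in (`assign_clips`: nearest template by cosine with a 0.7
rejection floor) sufficient to exercise the pipeline end-to-end, and the
fitting interface accepts label vectors from any external spike sorter.

## The surrogate-data generator

`make_benchmark_scenario()` builds the in-silico benchmark substrate with
known ground truth: 100 trials of each of 9 whisker stimuli plus 100 sham
trials, 600 ms trial windows with stimulus onset 200 ms in, a 4-channel
tetrode at 31.25 kHz, and independent Gaussian white noise of 10 uV SD
per channel. Single-unit spiking is a Bernoulli process at 1 ms
resolution whose success probability $p_i(t, W)$ depends on time and
stimulus, with the probability forced to zero for 2 ms after each spike
(absolute refractory period, enforced across trial boundaries); profiles
of real units can be estimated from spike trains with
`smooth_psth_boxfilter()` (a 5 ms box filter averaged across trials,
giving an instantaneous probability rather than a rate). Multi-unit
background is an inhomogeneous Poisson process -- no refractory period,
several spikes per millisecond possible. Spike times receive 0--1 ms
uniform jitter, realized at the nearest sample (32 us at 31.25 kHz, far
below every analysis window; the truth table records the realized
sample-quantized time so noiseless reconstruction is exact). Waveforms
are synthetic biphasic shapes (negative Gaussian lobe of ~0.25 ms FWHM,
delayed positive lobe of ~0.4 relative amplitude) with distinct
per-channel weight vectors per unit.

Deliberate calibration choices, fixed once:

* The five unit-mean peak-to-peak amplitudes are evenly spaced at 50, 65,
  80, 95 and 110 uV -- spanning the intended 50--120 uV band with a
  population mean of exactly 80 uV at $n = 5$, which an iid draw would
  not guarantee. Within-unit amplitude variability is a mean-one
  lognormal factor with CV 0.15.
* Evoked probability is an alpha-function bump peaking 10 ms after onset
  (support within the first ~30 ms), scaled so each unit's preferred
  stimulus evokes about two extra spikes per trial on top of 2 Hz
  spontaneous firing; Gaussian tuning (SD 1.5 stimulus steps) over the
  nine whiskers with staggered preferred stimuli yields a mean unit rate
  near 3 Hz.
* Multi-unit background: 12 Hz spontaneous plus an evoked bump averaging
  ~30 Hz over the post-stimulus window, with per-spike trough amplitudes
  drawn uniformly between 30 and 40 uV (3--4 noise SD, i.e. hovering at
  the usual detection threshold) and shapes drawn per spike from a pool
  of 64 random biphasic waveforms.
* Separate RNG streams drive spike sampling, jitter, amplitudes, shapes
  and noise, so the quintupled-noise scenario shares a bit-identical
  truth table with the baseline under the same seed. `rate_x5`
  multiplies all $p$ (clipped at 1) and $\lambda$ by five.
* Spike probabilities are zeroed in the first and last 2 ms of the
  recording so every truth spike admits a full clip window.

What the generator does *not* emulate: correlated or non-Gaussian noise,
electrode drift, spike-shape change during bursts, overlap-resolving
cluster structure, or the specific waveforms and PSTHs of any real
recording. Passing benchmarks therefore demonstrate the detection
machinery under controlled, idealized conditions -- not performance on
any particular in-vivo dataset. Because the unit amplitudes span 3.6--8.6
noise SD while the background sits at 3--4 SD, this surrogate is an
easier detection problem than a typical cortical tetrode recording;
absolute detection fractions here run above those reported for surrogates
derived from real recordings, and the benchmark's value lies in the
*comparisons* it supports (method ordering, threshold robustness), which
are insensitive to that offset.

## Scoring against ground truth

Truth spikes from two different single units within 0.5 ms of each other
are discarded before scoring (both members of the pair), since no
time-based matcher can attribute them unambiguously; the dropped fraction
is reported and stays small at baseline rates. Detections are then
matched one-to-one to truth spikes greedily by increasing time
difference. The matching tolerance defaults to 0.2 ms rather than reusing
the 0.5 ms ambiguity window: at permissive first-round thresholds
(2--2.5 SD) accepted noise crossings occur at several hundred Hz, and a
+-0.5 ms window would credit a large share of truth spikes to chance
coincidences, flattering precisely the regime where the fixed-threshold
method degrades. Trough-aligned event times are accurate to a few samples,
so +-0.2 ms (just over 6 samples) keeps genuine matches while suppressing
most chance credit; `tol_s` exposes the choice. Per-unit detection
fraction is matched truth spikes over truth spikes; multi-unit truth rows
participate in the matching (absorbing their own detections) but are not
scored.

`threshold_sweep()` repeats the whole pipeline over a grid of first-round
thresholds (2.0--6.0 SD by 0.5), building templates from truth-labeled
detected clips -- with known ground truth no clustering is needed to
evaluate detection -- and scores all three methods at each grid point. A
threshold yielding no labeled clips for any unit is recorded as
undefined (`NA`), never as zero. Inside the sweep, per-clip similarities
are read directly off the sliding traces at the clip start offsets (a
clip *is* the window starting there), which avoids materializing the
clip matrix of several hundred thousand noise crossings at the lowest
thresholds.

## Numerical choices

* $\lVert V(t)\rVert$ uses a rolling sum of squares with exact
  recomputation every 4096 samples and a clamp at zero, bounding drift
  and cancellation on silent spans; unit tests hold the production path
  to within $10^{-10}$ of an explicit-loop oracle.
* The first-round "crossing" is the first sample strictly below
  threshold following a sample at-or-above it, evaluated per channel;
  any channel may trigger, and one tetrode-wide shadow clock follows
  (whether the original per-channel clocks were shared is unknowable
  from the method's description; one clock avoids double counting a
  spike seen on several pads).
* Clip alignment re-extracts from the source trace so every aligned clip
  is genuine voltage, never padding; clips whose global trough is not
  interior to the window, or would shift beyond the pre-window, are
  dropped, and two crossings aligning to one trough collapse to one clip.
* Thresholds are computed as $\mathrm{mean}_c - k\,\mathrm{sd}_c$ on the
  full trace (plain SD, not a robust estimator -- `robust = TRUE` exists
  but is off by default), with the channel mean retained explicitly even
  though filtering makes it nearly zero.
* Edge events whose clip would leave the trace are dropped with a count,
  never zero-padded.

## Problem sizes

The shipped tests exercise the full-size benchmark -- three scenarios of
1000 x 600 ms trials (600 s of 4-channel voltage at 31.25 kHz each) with
a 9-point threshold sweep -- plus randomized small-instance oracle checks;
the whole suite runs in roughly a quarter hour on one core. Calibration
checks (rates, refractory, Poisson moments) use 200 s of 1 ms-resolution
sampling, where three standard errors distinguish the configured rates
comfortably. The acceptance script regenerates the baseline scenario and
its sweep from one seed.

## Known limitations

* Templates are fixed per fit; slow waveform drift requires refitting.
* The ROC rule optimizes balanced accuracy on first-round clips, which
  under-represents spikes the first round missed entirely; severely
  sub-threshold units can therefore still carry a pessimistic
  $\alpha_i$.
* Overlapping spikes from different units within the merge window
  resolve to a single detection; the benchmark sidesteps the ambiguity
  by filtering near-simultaneous truth pairs rather than solving it.
* The flat-binary + JSON-sidecar container is deliberately minimal;
  streaming acquisition and vendor formats are out of scope.
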