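---
title: "Methods: simulating and analysing responses to statistical outliers in tone streams"
author: "statoddball"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing responses to statistical outliers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

A listener exposed to a stream of pure tones whose frequencies are drawn at
random from a fixed distribution can, in principle, learn that distribution
implicitly and register tones from its tail as outliers. The
electrophysiological signature of such outlier detection is a mismatch
negativity (MMN)-like deflection: a negative-going evoked response roughly
100–200 ms after the unexpected event. The key experimental manipulation is
*statistical context*: the same physical probe tone is embedded in a stream
whose log-frequencies are Gaussian with either a narrow (SD 0.5 octaves) or a
broad (SD 1.5 octaves) spread around 500 Hz. A 2000 Hz probe (two octaves
above the centre) is far more improbable under the narrow context, so a
context-sensitive system should produce a deeper MMN there — even though the
probe itself arrives at the same 10% rate in both streams.

`statoddball` implements this entire study as a *synthetic, fully testable
pipeline*: a stimulus generator, a multichannel sensor-recording generator
with planted evoked components, and the complete analysis chain (evoked-field
preprocessing, mass-univariate spatio-temporal statistics, a max-SNR spatial
filter, and a frequency-local adaptation analysis with permutation tests).
No real recordings are involved; the purpose is a reference implementation of
the analysis machinery whose every stage can be validated against known
ground truth.

## Stimulus model

Tones arrive every 500 ms (SOA). Each tone is independently a standard probe
(probability 0.10, at the context centre, log2-offset 0), an odd probe
(probability 0.10, two octaves above the centre, 2000 Hz), or a contextual
tone (probability 0.80) whose log2-frequency is drawn from N(0, sigma^2) in
octave units. The overall frequency distribution is therefore a mixture of a
Gaussian and two point masses, deliberately so: probes must be frequent
enough to average. All frequencies are carried internally in log2-octave
units relative to the centre; Hz appear only at I/O boundaries, because every
distributional statement in the design is about log-frequency.

Probe insertion is i.i.d. per tone. Pseudo-random insertion of probes does
not by itself pin down a spacing constraint; independent assignment is the
simplest mechanism consistent with it, and `generate_sequence(spaced_probes
= TRUE)` provides the plausible alternative (no two adjacent probes) for
sensitivity analyses.

A useful analytic consequence of the design, exposed as
`band_probability()`: under the broad context the probability that a
contextual tone lands within a semitone (1/12 octave) of the odd-probe
frequency is `pnorm((2 + 1/24)/1.5) - pnorm((2 - 1/24)/1.5)` — just under
1%. Frequency-local stimulation near the probe is rare even in the broad
context, which is what makes the adaptation analysis informative.

## Recording model

`simulate_recording()` plants two evoked components on a quasi-uniform disk
layout of (by default) 274 sensors at 600 Hz:

* an **auditory component**: a Gabor kernel (latency 100 ms, envelope SD
  20 ms, 10 Hz carrier, amplitude +1.5) on a fixed unit-norm spatial
  pattern, evoked by *every* tone — the M100 stand-in;
* an **MMN-like component**: a negative Gaussian bump (latency 150 ms,
  inside the conventional 100–200 ms MMN window; envelope SD 35 ms) on a
  second fixed pattern, evoked by probe tones only.

The MMN amplitude is phenomenological, not normative:

```
A[kind, context] * (1 - rho[context] * exp(-N_a / tau))
```

with the base table `A` (sensor units) defaulting to

| | narrow | broad |
|---|---|---|
| standard probe | -0.10 | -0.55 |
| odd probe | -1.30 | -0.60 |

and `rho = (narrow 0.05, broad 0.55)`, `tau = 4` tones. The table encodes
the qualitative effect directions the study design predicts: odds deeper
than standards everywhere (surprise); the odd-probe MMN deeper in the narrow
context (interaction); standard-probe responses smaller in the narrow
context; and local adaptation (the `rho`/`tau` saturating recovery in the
number `N_a` of consecutive preceding tones outside a 1/3-octave window)
substantial in the broad context and nearly absent in the narrow one. The
magnitudes are otherwise arbitrary — no quantitative effect sizes in sensor
units are available to emulate — so all downstream acceptance checks are
direction-of-effect checks, not amplitude checks. The generator defines
`N_a` for a standard probe against a window centred at the standard's own
frequency (the analysis-side definition only covers odd probes); adaptation
ground truth uses the 1/3-octave (ERB-like) window, while the analysis probes
a grid of windows, giving a realistic model/analysis mismatch.

The two spatial patterns are random unit vectors with cosine overlap 0.6,
reflecting partially shared generators of the auditory and mismatch
responses; a filter tuned to evoked SNR then inevitably captures a
substantial fraction of the MMN, as it should.

Noise is an AR(1) process (coefficient 0.95 at 600 Hz) mixed through a
random rank-40 spatial matrix (marginal SD 0.8 per channel), plus
independent white sensor noise (SD 0.25). This is the simplest model that
makes the band-pass, baseline, and spatial-filtering stages non-trivial:
strong low-frequency power, genuine spatial correlation with a full-rank
noise covariance. There is no 1/f tail, no line noise, no artefacts, no
inter-subject variability in patterns or amplitudes — so passing tests
validate the *machinery*, and say nothing about robustness to those
real-data features.

## Preprocessing

The pipeline order is fixed: zero-phase band-pass of the *continuous*
record, downsample 600 to 200 Hz, epoch, baseline-correct. Filtering the
continuous data avoids per-epoch filter transients (epoching first and
filtering 450 ms snippets would contaminate a third of each epoch at these
cutoffs).

Numerical choices, pinned so tests are exactly reproducible:

* **Filter realization.** Zero-phase (forward–backward) Butterworth cascade:
  2nd-order high-pass at 0.5 Hz plus 4th-order low-pass at 30 Hz. A single
  band-pass section at a normalized low edge of 0.5/300 is numerically
  fragile in transfer-function form, and a 4th-order band-pass run
  forward–backward only reaches about -19 dB at 50 Hz; the cascade is robust
  and gives ~-36 dB there while keeping 10 Hz within 5%. Edge effects are
  suppressed by odd-reflection padding (3/lo seconds). The inner loop is
  compiled (Rcpp) because 274-channel, 13-minute blocks make per-channel R
  filtering the pipeline bottleneck.
* **Downsampling** decimates by the integer factor 3 after an anti-alias
  low-pass (4th-order Butterworth at 80 Hz, zero-phase); when the record has
  already been band-passed well below the target Nyquist the redundant
  filter is skipped (`antialias = "auto"`).
* **Epochs** run from -100 to +350 ms with *both* end points included:
  exactly 91 samples at 200 Hz, matching the 64 x 64 x 91 spatio-temporal
  volume geometry. Events whose window would leave the record are dropped
  and counted.
* **Baseline** is the closed interval [-100, 0] ms; the 0 ms sample belongs
  to the baseline. Nothing in the design forces either convention; this one
  is pinned so results are exactly reproducible.

## Scalp-level statistics

Condition ERFs (`average_erf`) are converted to spatio-temporal volumes:
each time bin's sensor field is interpolated onto a 64 x 64 grid over the
fixed square [-1, 1]^2 and the images are stacked in peristimulus order.
Interpolation is exact thin-plate-spline interpolation through the sensor
positions — the standard choice for scalp topographies — computed once per
layout as a pixels-by-channels operator, so volumization is a single matrix
product and is exactly linear in the data. TPS interpolation reproduces
affine fields exactly, which the tests exploit. Pixels outside the sensors'
convex hull are masked.

The within-subject model is the mass-univariate GLM with one regressor per
condition (`sl`, `sh`, `ol`, `oh` = standard/odd x low/high variance) plus
two nuisance regressors (block indicator, block-context assignment). With
context blocked, the nuisance columns are linear combinations of the
condition columns; they are orthogonalized against the condition regressors
and annihilated columns are dropped, leaving condition effects estimable —
the standard confound-coding resolution. Because volumization is linear,
betas are fitted in channel space and volumized afterwards; this is
algebraically identical to fitting per-epoch volumes and avoids
materializing thousands of volumes. A condition-average mode
(`fit_glm(mode = "average")`) is also provided.

Contrasts: **surprise** `(b_sl + b_sh) - (b_ol + b_oh)` and **interaction**
`(b_ol - b_sl) - (b_oh - b_sh)`; the weight vectors are orthogonal. Group
inference is a one-sample t across subject contrast volumes with family-wise
correction by sign-flip max-|t| permutation (the two-sided |t| max-statistic
is the permutation analogue of a one-sample F for a single contrast, F =
t^2). Random-field-theory corrections were deliberately not used: the
permutation approach makes no smoothness assumptions, needs no external
dependency, and tests the same inferential claim (corrected p < 0.05
somewhere in the volume). The add-one rule `p = (1 + #{max >= |t|}) / (1 +
n_perm)` keeps p-values positive and the test valid.

## Max-SNR spatial filter

For each condition `c`, with epoch measurements `x_n(t)` and condition mean
`xbar_c(t)`:

* signal power: `S_c = (1/T) sum_t xbar_c(t) xbar_c(t)'`
* noise covariance: `V_c = (1/(N_c T)) sum_n sum_t (x_n(t) - xbar_c(t))
  (x_n(t) - xbar_c(t))'`

`S` and `V` average the four condition matrices; the filter is the leading
eigenvector of the generalized problem `S w = lambda V w`, solved by
whitening through a Cholesky factor of `V + ridge I` and a symmetric
eigendecomposition. The ridge (default `1e-6 * trace(V)/channels`) guards
near-singular noise covariances; the whitened route through `V^{-1/2}` is
kept in the test suite as an independent oracle. Sums run over the full
epoch; restricting to post-stimulus samples is a config choice the package
exposes through the epoch window rather than a hidden flag. The filter is
fitted once on all subjects pooled (averaged condition matrices), i.e. one
filter common to all participants — by design, the filter optimizes evoked
SNR for all four probe conditions jointly and is *not* tuned to accentuate
condition differences.

An eigenvector's sign is arbitrary. The weights are oriented so that the
filtered grand-mean odd-minus-standard *difference* ERF is negative on
average in 100–200 ms. Orienting on the odd ERF itself would be ill-posed:
the positive auditory deflection also lies in that window and can dominate.
The difference trace cancels the auditory component and isolates the MMN,
whose deflection is made to point downward. The effective forward pattern of
the extracted component is `V w`.

## Local adaptation analysis

Each odd probe is labelled with `N_a`: the number of *consecutive*
immediately preceding tones (of all types, probes included) outside a window
of full width Delta octaves centred at the odd-probe frequency; the count
stops at the first in-window tone. The consecutive-run definition (rather
than a count within a fixed lookback) is what makes statements like "the 15
preceding tones, spanning 7.5 s, were all frequency-distant" well defined,
and it is the reading this package adopts; a brute-force scan over random
sequences is the test oracle.

Responses are grouped per context either by threshold (`N_a >= g`,
overlapping groups, counts weakly decreasing) or by disjoint bins. Default
thresholds are {0, 1, 2, 4, 8, 15} and default windows Delta in {1/3, 2/3,
1, 4/3, 5/3} octaves — 1/3 octave is roughly one equivalent rectangular
bandwidth (ERB), and 15 spans 7.5 s at the 500 ms SOA. Only the 1/3-octave
window and the value 15 are anchored in the design; the remaining grid
points are configuration. The peak of each group ERF is its minimum within
50–250 ms post-onset (a pinned choice; any reasonable post-stimulus
neighbourhood of the MMN latency would do), and each individual response
contributes the
mean of its samples within ±30 ms of that latency.

Contexts are compared with a one-tailed sampled permutation test on the
per-response peaks: statistic `d = mean(broad) - mean(narrow)` (peaks are
negative; a deeper narrow MMN makes `d` positive), 2500 label permutations,
add-one correction. The direction is pinned to "narrow deeper than broad";
each (Delta, threshold) pair is tested at an independent 0.05 level. For
group sizes small enough to enumerate, the sampled p-value is checked
against exhaustive enumeration in the tests, and its null distribution is
checked for (super-)uniformity — the add-one rule makes the test slightly
conservative, never anticonservative.

## Orchestration, seeds, and problem sizes

`run_experiment()` reproduces the whole study from one master seed: every
stochastic stage (sequence, noise realization, permutations) draws a child
seed via a deterministic hash (`child_seed`), so stages are independently
reproducible and the full report is bit-identical under a fixed master seed.
Default scale: 18 subjects, two 13-minute blocks each (1560 tones per
block), 274 channels at 600 Hz, two counter-balanced context orders. The
runner processes one subject at a time and retains only per-subject contrast
volumes, covariance pairs, condition ERFs, and odd-probe epochs, keeping
peak memory around 3–4 GB; a full default run takes a few minutes of CPU
time. Unit tests run the same code at reduced scale (fewer channels,
subjects and tones); the acceptance suite runs the default scale once.

## Limitations

* The generator is phenomenological. It contains no head model, no dipole
  forward fields, no source geometry; "patterns" are abstract unit vectors.
  An optional surprise-proportional amplitude mode is exploratory only.
* No artefacts (blinks, movement, line noise), no 1/f spectrum, no
  between-subject variability; group inference therefore tests the
  machinery under exchangeability, not realistic inter-subject dispersion.
* Serialization is CSV/JSON only; there is no binary container I/O.
* The scalp-map geometry is a synthetic disk layout, not an azimuthal
  projection of a real helmet; volume coordinates are in layout units.
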