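---
title: "Behavioral and inter-brain synchrony analysis for piano-duet hyperscanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral and inter-brain synchrony analysis for piano-duet hyperscanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duetsync)
```

## The scientific problem

When two pianists perform a melody together, their keystroke timing behaves
like a pair of coupled oscillators: each player has a spontaneous (solo)
tempo — a natural frequency — and coordination in the duet reflects the
difference between those natural frequencies (the *detuning*). On the neural
side, self-paced rhythmic performance is accompanied by EEG oscillations at
the performance rate, strongest over fronto-central (auditory-motor) sites,
and the slow amplitude fluctuations of those oscillations may become
correlated between partners who play in synchrony.

`duetsync` implements the full measurement chain for this question:

1. **Behavior** — quarter-note inter-onset intervals (IOIs), performance
   rates in Hz, and signed/absolute duet asynchronies normalized by the duet
   IOI, after excluding repetitions with added or deleted tones.
2. **Spectral entrainment** — Welch power spectral density over fixed 9-s
   epochs, log transform, local noise normalization, rate-aligned spectra,
   fronto-central ROI averaging, and Wilcoxon signed-rank peak tests.
3. **Oscillation extraction** — spatio-spectral decomposition (SSD) spatial
   filters fitted on solo recordings and applied to duet recordings.
4. **Inter-brain coupling** — narrowband amplitude envelopes at each pair's
   duet rate, resampled onto the melodic event grid, correlated between
   brains (AECs), and compared with a surrogate re-pairing null by an exact
   binomial test.
5. **Synthetic data** — a generator of coupled duet timing and dual-brain
   EEG with known ground truth, so every stage above is testable by
   parameter recovery without access to any recordings.

## The timing model

The simulator is a linear phase-correction timekeeper operating on the beat
grid. With beat periods $T_L$, $T_F$ (ms) and asynchrony
$A(n) = t_L(n) - t_F(n)$ at beat $n$:

$$t_L(n+1) = t_L(n) + T_L + \epsilon_L(n) - \beta A(n), \qquad
  t_F(n+1) = t_F(n) + T_F + \epsilon_F(n) + \alpha A(n),$$

where $\alpha$ is the follower's correction gain, $\beta$ (default 0) the
leader's, $\epsilon$ is timekeeper noise, and emitted onsets add
non-propagating motor noise. The asynchrony recursion
$A(n+1) = (1-\alpha-\beta)A(n) + (T_L - T_F)$ contracts (for
$0 < \alpha + \beta < 2$) to the fixed point

$$A^\ast = \frac{T_L - T_F}{\alpha + \beta},$$

the closed-form detuning law the test suite verifies exactly. Two modelling
choices deserve comment:

* **Beat-grid correction.** Correction is applied once per beat, not once
  per tone. Off-beat eighth notes are emitted at the temporal midpoint of
  the surrounding beat times (isochronous subdivision), and half notes
  occupy two beats of the internal grid. This keeps the fixed point exact at
  every co-performed event regardless of the local rhythm, which would not
  hold if the correction gap varied with note value.
* **Phase correction only.** Human followers also adapt their period
  (frequency entrainment), which is why real duets show asynchronies much
  smaller than detuning/$\alpha$ with plausible gains. We deliberately omit
  period correction: the linear model has a closed-form law to test against,
  and the qualitative predictions (asynchrony monotone in detuning; leader
  dominates the duet tempo) are preserved. Synthetic cohorts therefore show
  *larger* normalized asynchronies than trained pianists would.

The melody is the 32-tone round "Frère Jacques" in C major (20 quarter
notes, 4 half notes, 8 eighth notes; 32 beats; G3–A4), with the first 8
tones — all quarters — serving as the leader's solo count-in; the follower
joins at the 9th tone of each trial's first repetition. Default cohort
conditions: 6 duet trials × 4 repetitions per condition (24 repetitions),
3 solo trials per performer (12 repetitions), follower gain $\alpha = 0.5$,
timekeeper/motor noise 10/4 ms, 4% pitch-error probability per repetition,
and natural periods drawn per performer from $\mathcal N(470, 65^2)$ ms
truncated to 300–650 ms, matching the spread of spontaneous tempi reported
for trained pianists (pair means roughly 300–600 ms, mean partner
difference ≈ 74 ms).

## Error exclusion

Repetitions containing *added or deleted* tones are excluded everywhere;
*substituted* pitches are retained because they do not disrupt the timing of
the sequence. Classification is a global Needleman–Wunsch alignment of
played against notated pitches (match +1, mismatch −0.25, indel −1; ties
resolve toward substitution), so a substitution is always preferred over an
insertion/deletion pair and the alignment also yields the event pairing used
for asynchronies. The follower's count-in repetitions are scored against the
post-count-in template (tones 9–32).

## Spectral measures

All bin arithmetic is anchored on one inference: at 500 Hz with 9-s (4500
sample) epochs, the printed 0.061 Hz resolution is produced uniquely by
`nfft = 8192`, the next power of two. Each epoch is one Welch segment — a
Hanning-windowed, zero-padded modified periodogram (overlap never enters).
Per-epoch spectra are log-transformed (natural log; any base shifts
normalized values by a scalar) and averaged per channel. Noise
normalization subtracts from each bin the mean of its ±1..±3 neighbors
(±0.183 Hz); a locally smooth background cancels exactly, a single-bin line
of height $h$ maps to $h$ at the line and $-h/6$ at its six neighbors. Edge
bins use the neighbors that exist and are flagged. Rate-aligned windows
keep the 49 bins (2.99 Hz) centered on the bin nearest the pair's duet
rate, ties resolving to the lower bin. The peak test is a paired Wilcoxon
signed-rank of the center bin against the mean of the surrounding ±8 bins,
reported as a normal-approximation z (with tie correction) or, for n ≤ 25,
via the exact null distribution.

Whether the ±3-bin noise mean should exclude immediately adjacent bins is a
live convention question in frequency tagging; we include offsets ±1..±3
and expose the half-width in `spectral_config()`.

## SSD and component selection

SSD maximizes band power against two flanking bands through the generalized
eigenproblem $S w = \lambda N w$ ($S$: covariance of the 1.5–3.5 Hz
band-passed data; $N$: summed covariance of the flanks). Flank geometry is
not dictated by convention, so we default to 1-Hz flanks separated from the
band by 0.5-Hz gaps, configurable. Band-passes are zero-phase 2nd-order
Butterworth filters; because every band of interest lies below 6 Hz, the
recording is antialias-decimated to 50 Hz before covariance estimation,
and the band-pass for covariance purposes is applied as $|H(f)|^2$ in the
frequency domain (the steady-state equivalent of forward–backward
filtering). The eigenproblem is solved by whitening $N$ and symmetric
eigendecomposition; a rank-deficient $N$ receives a fixed ridge
($10^{-6}\,\mathrm{tr}(N)/d$) with a warning. Filters are paired with
forward patterns ($S w$, column-normalized), which are the interpretable
topographies.

The published procedure selects one component per participant *visually*;
our automated proxy scores each leading component by (band/flank power of
its time course) × (fraction of absolute pattern mass on the FC1/FC2/Fz/Cz
ROI) and fixes the sign so the mean ROI pattern loading is positive. A
covariance-based filter cannot sense overall data polarity, so the sign
convention pins the filter (and hence the amplitude envelope, which is what
downstream analysis consumes); the selected index is overridable.

Filters are fitted on solo recordings and applied to duet recordings — an
independent data set from the same performer.

## Envelopes, resampling, and the surrogate null

For each duet condition the selected filter's time course is band-passed at
the pair's duet rate ±0.183 Hz (2nd-order Butterworth, zero-phase; applied
after projection, which is equivalent to filtering the multichannel data
first by linearity), epoched per melody repetition with 2.5-s pads,
antialias-decimated to 100 Hz, Hilbert-transformed, and the 2.5-s tails are
trimmed. Envelope time is then warped onto the melodic event grid: the
minimum eighth-note-equivalent inter-onset sample count $m$ across
repetitions (and across both partners of whichever pairing is being
correlated) sets the grid — eighths map to $m$ samples, quarters to $2m$,
halves to $4m$, 64·m samples per repetition — using shape-preserving
piecewise-cubic (pchip) interpolation. Per-repetition Pearson correlations
are Fisher-z transformed, averaged within condition, then across
conditions, and back-transformed; for each trial's first repetition only
samples from the 9th event's grid anchor onward enter (both partners are
playing from there, inclusive of the anchor sample). Perfect correlations
are clipped at `atanh(0.999999)` and flagged.

The chance level for "two people playing the same melody" is estimated by
re-pairing each leader with every follower except their own (n−1
surrogates per leader and condition; 19 in a 20-pair cohort). Surrogate
members' envelopes are re-resampled to the surrogate pairing's common grid
before repetition-k is correlated with repetition-k; each pair's surrogate
distribution is summarized by its Fisher-z mean. The cohort comparison is
an exact one-sided binomial test of how many pairs' observed values exceed
their surrogate mean (ties count as failures; null p = 0.5). The paper's
printed worked example — 15 of 20 pairs, p = 0.02 — is the tail sum
21700/2^20 and is only reproduced one-sided, which fixes the test's
direction a priori.

Envelope means are not detrended before correlation: Pearson centering
makes per-repetition level offsets irrelevant.

## What the generator emulates — and what it does not

Dual-brain EEG is synthesized as
`topography ⊗ (A(t)·cos(2π f_duet t + φ)) + 1/f background + white noise`,
with an optional 10 Hz occipito-parietal distractor. The two partners'
amplitude processes mix a shared and a private smoothed Gaussian process as
$\sqrt\rho\,z_{sh} + \sqrt{1-\rho}\,z_{priv}$, mapped to positive
amplitudes by `softplus(2 + z/2)` — a map chosen over rectification because
it is smooth (Hilbert-friendly) and operates in the softplus's near-linear
region, so the realized envelope correlation stays within sampling error of
the requested ρ. Envelope fluctuations are band-limited to 0.4 Hz,
matching the seconds-scale amplitude dynamics visible in delta-band
performance EEG. The source gain is set so its power within the ±0.183 Hz
analysis band at the maximum-topography channel sits `snr_db` above the
background's; `snr_db = -Inf` yields noise-only recordings for
false-positive studies.

Not emulated: eye-blink/EMG artifacts (artifact correction is out of
scope — the pipeline accepts clean data), volume-conduction leakage between
brains (impossible by construction), keystroke biomechanics, MIDI velocity,
and tempo drift within repetitions. Passing recovery tests on this
generator therefore demonstrates the *estimator chain* is correct, not that
real duet EEG contains envelope coupling of any particular size.

## Numerical choices

* Times are float ms (behavior) and 0-based integer samples with half-open
  epochs (EEG), everywhere.
* `nearest_bin` ties resolve to the lower bin; deterministic.
* The narrowband envelope filter attenuates background but also the
  envelope's own fluctuations above ≈0.18 Hz; since shared and private
  components attenuate equally, the recovered AEC is attenuated mainly by
  residual background envelope noise. At a 15 dB in-band SNR the pipeline
  recovers pooled AECs within ≈0.1 of the generating ρ.
* All randomness descends from a root seed through named substreams
  (`substream_seed`), so each stage is independently reproducible and
  re-runs are byte-identical.
* Exclusion thresholds: envelope grids coarser than 4 samples per eighth
  note are rejected; repetitions whose padded envelope window leaves the
  recording are dropped with a warning, as are 9-s epochs that would run
  past the end of a recording.

## Problem sizes used by the acceptance suite

Cohort-level checks simulate at the study's structural conditions but
scale counts where full size adds nothing statistically: behavioral
cohorts use 20 pairs × 100 seed batches (1 trial × 4 repetitions each);
entrained spectral cohorts use 20 participants × 4 epochs at 5 dB; the
false-positive study uses 200 cohorts of 20 participants × 12
noise-only epochs (the solo-condition repetition count); AEC recovery uses
20 pairs per ρ level at 8 repetitions per condition and 15 dB ("high
SNR"), with the surrogate comparison at ρ = 0.6. The acceptance script
(`scripts/acceptance.R`) re-runs the same machinery at comparable sizes.

## Known limitations

* The phase-correction-only timing model exaggerates asynchronies relative
  to human pairs (no period correction; see above).
* The automated SSD component selection approximates, but is not, the
  published visual selection.
* Surrogate re-pairing is performed within condition and then averaged,
  following the stated procedure; crossing leader-order conditions before
  averaging would be a different (also defensible) null.
* Native I/O is TSV (events) and flat binary + JSON (EEG); EDF/XDF
  ingestion is not provided.
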