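---
title: "Anechoic demixing of movement trajectories: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anechoic demixing of movement trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anechoid)
```

## The model

Multichannel kinematic recordings — for example one joint-angle trajectory
per trial and joint — often look like scaled and *time-shifted* copies of a
small number of shared waveforms. `anechoid` fits the anechoic mixing model

$$x_i(t) = \bar{x}_i + \sum_{j=1}^{N} a_{ij}\, s_j(t - \tau_{ij}),$$

where the $s_j$ are $N$ shared source waveforms ("movement primitives"),
$a_{ij}$ is the weight of source $j$ on channel $i$, and $\tau_{ij}$ is a
per-channel, per-source time delay. "Anechoic" is borrowed from acoustics:
each source reaches each sensor once, with one amplitude and one delay, with
no reverberation. Instantaneous decompositions (PCA, ICA) are the special
case $\tau_{ij} \equiv 0$; on data in which functionally identical waveforms
recur at different times across channels they must spend extra components
to absorb the shifts, which is exactly the comparison this package's PCA
baseline (`fit_pca()`, `pca_vaf_sweep()`) makes visible.

Because the signals are smooth and band-limited, every channel and source is
represented by a truncated Fourier series of order $F$ (`fourier_fit()`),
and a delay becomes a per-harmonic phase ramp
(`fourier_delay()`): $c_k \mapsto c_k e^{-2\pi i k \tau / T}$. Two
consequences matter in practice:

* **Delays are circular over the trial window.** The Fourier representation
  periodizes the record, so a delayed source wraps around the ends. Trials
  should therefore span complete movement cycles (the conventional
  normalization used here is 350 samples covering two gait cycles,
  `resample_and_smooth()`).
* **Everything happens on $2F$ numbers per channel.** All fitting operates
  on the complex coefficients of harmonics $1..F$; channel means are kept
  aside and restored at reconstruction.

## The fitting algorithm

`fit_fada()` alternates three exact conditional updates until the
coefficient-domain residual stalls:

1. **Magnitude demixing** (`magnitude_demix()`): the non-negative matrix of
   coefficient magnitudes $|c_{ik}|$ is factorized as
   $|A|\,|S|$ by seeded multiplicative updates (Frobenius objective, best of
   three starts). This exploits that a delay changes only phases, never
   magnitudes, and yields the initial weights and source spectral
   magnitudes. We use a plain non-negative factorization here because the
   step only requires one; the alternation below, not this step, determines
   the final sources.
2. **Phase refitting** (`update_phases()`): with magnitudes, weights and
   delays fixed, the source phases minimize the Frobenius residual by
   coordinate descent — each update has a closed form, so the objective
   never increases.
3. **Delay and weight estimation** (`estimate_weights_delays()`): for each
   source in turn, every channel scans the full circular lag grid; each
   candidate lag is scored by the channel's explained variance under
   *jointly* least-squares-refitted weights for all sources (closed form via
   precomputed Gram tables). This matters: plain residual cross-correlation
   is systematically misled when sources overlap spectrally, because energy
   belonging to one source masquerades as a correlation peak for the other.
   The winning lag is refined on a 0.1-sample local grid with a parabolic
   vertex step, so sub-sample delays are reported. With the sources fixed
   and exactly two of them, an exhaustive scan over all integer lag pairs is
   also available (`exhaustive = TRUE`), and is enabled automatically on
   small problems.
4. **Source refinement**: given weights and delays, the full complex source
   coefficients have a per-harmonic least-squares solution. This step — the
   natural M-step of the alternation — is what lets noiseless realizable
   data be reconstructed essentially exactly; refitting phases alone against
   fixed factorized magnitudes cannot, because $|x| \ne |A||S|$ once spectra
   overlap.

Each of the 25 restarts (the conventional number for this family of
algorithms; `n_restarts`) runs a short schedule first: several iterations
with the source magnitudes locked at the factorization — delays crystallize
much more robustly when the sources cannot yet deform to absorb misfit —
followed by a few released iterations. The lowest-residual restarts (plus a
nested warm start, below) then run to convergence and the best solution
wins, ties broken by restart index. Restart 1 uses a deterministic
data-driven start (zero delays, source phases from the weight-averaged data
coefficients); the rest draw phases uniformly on $(-\pi, \pi]$ and delays
uniformly on $(-T/4, T/4)$.

Reported models are put in a canonical form so the model's inherent
ambiguities (source permutation, sign, scale, delay offset) never leak into
comparisons: unit-$L^2$-norm sources ordered by explained variance with the
dominant extremum positive, delays wrapped to $[-T/2, T/2)$ with zero
weighted mean per source.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `order` ($F$) | 10 | highest retained harmonic; `choose_fourier_order()` picks the smallest band holding 99.9% of spectral energy, capped at 10 for 350-sample gait windows |
| `n_restarts` | 25 | random restarts; best-of-restarts is kept |
| `max_outer_iter`, `tol` | 200, 1e-6 | outer alternation cap and relative-improvement stop |
| `nonneg_weights` | `FALSE` | constrain reported weights $\ge 0$; the optimization itself always runs unconstrained (sign freedom helps it cross poor basins) and the constraint is applied in a final delay/weight re-estimation against the canonical sources. Use it when the mixing is known non-negative, as in the default synthetic template |
| `warm_start` | `NULL` | seed one extra run from a smaller fitted model (used by `vaf_sweep()` so the VAF curve is monotone in $N$) |

## Choosing the number of primitives

`vaf()` measures reconstruction quality as the percentage of variance
accounted for,
$100\,(1 - \|X - X_{rec}\|_F^2 / \|X - \bar{X}\|_F^2)$, with $\bar X$ the
row-means matrix, always on the original signal scale (the PCA baseline
de-standardizes before the comparison so the two curves are commensurable).
`vaf_sweep()` fits $N = 1..5$ and `scree_select()` locates the elbow by the
regression procedure: fit a line to the whole curve, drop the leftmost point,
refit, and select the smallest $N$ whose trailing segment has mean-square
residual below 0.001 (VAF on the 0–1 scale). One addition was necessary to
make the criterion well posed: a perfectly straight *rising* curve has zero
regression residual everywhere but no elbow, so a segment also has to be
saturated — fitted slope below 0.01 per added component — before it can be
selected. Without the saturation check the criterion could never return "no
solution", which it demonstrably must for gradually rising curves such as
the PCA baseline's. Both thresholds are arguments.

`cross_validate()` splits by trial (all channels of a trial stay together,
stratified by condition label when present), fits sources on the training
fraction (default 80%), then freezes them and re-estimates only weights and
delays on the held-out trials; the test VAF is the honest generalization
measure. `align_sources()` matches two source sets by permutation (exhaustive
up to 4 sources), circularly shifts each pair so the maximum peaks coincide
(or to the correlation-maximizing lag with `method = "max_corr"`), optionally
flips signs, and reports the post-alignment correlations.

## The synthetic generator

`make_mixture_dataset()` draws data *from the model*, with every hidden
parameter returned alongside, so each pipeline stage can be tested against
ground truth. The default `gait_reach_config()` emulates the structure of a
reach-during-walking experiment: six channel groups (right/left shoulder,
hip, knee flexion) times 40 trials, 350 samples at 120 Hz spanning two gait
cycles, and two sources —

* a *discrete* bell-shaped bump (`make_discrete_source()`, wrapped Gaussian,
  centre 0.45, width 0.10 of the window) loaded mainly on the right-shoulder
  channels: the reach;
* a *rhythmic* waveform with one flexion peak per gait cycle, two per
  window (`make_rhythmic_source()`, wrapped Gaussian peaks, second/first
  height ratio 0.8), with weights growing toward the lower body and the
  left-side delay offset by half a gait cycle: the gait.

Per-(channel, source) delays are Gaussian around the group means (SD 0.08 s,
about 10 samples — comparable to the stride-to-stride timing jitter of
natural walking) and i.i.d. Gaussian noise with SD 0.05 is added (sources
are unit-peak, so roughly 5% noise). Both peaks are wrapped Gaussians rather
than low-order cosines on purpose: real joint-angle cycles carry spread
harmonic content, and a pure-tone rhythmic source would make the division of
its single harmonic between the two sources almost unidentifiable — a
degeneracy of the waveform, not of the method. `make_gait_marker_fixture()`
complements this with vertical toe/heel marker channels and a hand-distance
channel whose event times are known analytically.

What the generator does *not* emulate: amplitude variation of the weights
across trials, non-Gaussian delay distributions, channel-correlated noise,
drift or incomplete cycles. Passing tests therefore demonstrate correctness
of the machinery under the model's own assumptions, not robustness to every
pathology of real motion capture.

## Gait events and reach timing

`detect_foot_events()` implements the kinematic event definitions: events
sit at sign changes of the (zero-phase low-pass filtered, default 10 Hz)
vertical marker velocity, computed from position by central differences;
crossing times are interpolated linearly between bracketing samples and a
0.2 s refractory period suppresses noise-induced double crossings. A toe
marker's downward-to-upward crossing is a toe lift-off; a heel marker's
upward-to-downward crossing is a heel strike (both directions exposed via
`marker = "both"`). `gait_cycle_durations()` (lift-to-lift of the same
toe), `stance_fractions()` (strike to successive lift, as % of the enclosing
cycle) and `reach_timing()` (global hand-distance maximum, duration between
the bracketing local maxima, signed couplings to the next four foot events)
implement the standard timing measures. On noisy fixtures with 1 mm marker
noise the detector recovers event times well within the ±25 ms accuracy
conventionally accepted for automatic gait-event detection.

## Numerical choices and degenerate inputs

* Missing samples at load time: interior gaps of up to 5 samples are filled
  linearly; longer or boundary gaps are errors, never silently passed.
* `resample_and_smooth()` chooses the smoothing-spline penalty by
  generalized cross-validation (so noiseless channels pass through almost
  unchanged) and interpolates the smoothed values with a cubic spline;
  endpoints are preserved to well under 1% of the channel range.
* All-zero channels get weight 0 and the canonical delay 0. Zero-variance
  channels are a hard error in the PCA path (their correlation is
  undefined) and are reported by label.
* Ill-conditioned weight systems (nearly collinear delayed sources) are
  stabilized by a tiny relative ridge ($10^{-9}$ of the source Gram
  diagonal).
* Ties across restarts (residuals within $10^{-12}$) resolve to the lowest
  restart index; all randomness flows from one integer seed, and identical
  seeds give bit-identical fits.
* The coarse delay grid uses a 2-sample step when $T \ge 16F$ — the
  correlation function against an order-$F$ series cannot have features
  narrower than $T/2F$ samples — and the local 0.1-sample grid plus
  parabolic refinement restores sub-sample resolution in every case.

## Problem sizes used in the shipped analyses

The packaged tests and the acceptance script run the full study conditions
for the headline checks — 40 trials × 6 channel groups × 350 samples, 25
restarts, orders 1–5 — and deliberately smaller instances (6–12 trials,
fewer restarts) for the many per-operation unit tests, where the properties
under test are scale-free. Oracle comparisons (exhaustive lag grids, full
eigendecompositions) use records of 64–200 samples so the brute-force
reference itself stays exact.

## Known limitations

* The model is exactly the single-delay anechoic mixture: no multi-tap
  (convolutive) mixing, and one delay per channel-source pair.
* Per-channel weights on channels where a source is weak are the least
  stable quantities: the delay search can lock onto noise there, which
  inflates weight scatter. Weight patterns averaged within channel groups
  (joints) are far more reproducible than single-channel weights, and that
  is the level at which weighting coefficients are conventionally reported.
* Alternating optimization finds local minima; the restart schedule makes
  the selection robust in practice, but best-of-25 is a heuristic, not a
  guarantee. The residual and the full restart error vector are returned so
  convergence quality can always be inspected.
* Uncorrelatedness of sources and independence of delays are assumptions of
  the derivation; they are used here only implicitly (the factorized
  magnitude initialization), never enforced as hard constraints.
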