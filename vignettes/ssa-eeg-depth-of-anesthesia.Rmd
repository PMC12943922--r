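---
title: "SSA mode decomposition of anesthetic EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSA mode decomposition of anesthetic EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssaeeg)
```

## The problem

Frontal EEG under general anesthesia is non-stationary: over the ten
minutes preceding emergence, delta-band slow waves and 10–12 Hz alpha
spindles give way to low-amplitude beta activity. Fourier methods trade
temporal resolution for frequency resolution and impose fixed bands.
`ssaeeg` instead decomposes short sliding epochs by **singular spectrum
analysis (SSA)** — a nonparametric, basis-free matrix decomposition — and
characterises each resulting mode by its Hilbert instantaneous frequency
and amplitude. The per-epoch mode features are then regressed against a
0–100 depth-of-anesthesia index (BIS) by ordinary least squares.

## The decomposition

Each recording is sliced into 3-s epochs (384 samples at 128 Hz) advanced
by 2 s, so consecutive epochs share 1 s. The leading $N = 383$ samples of
an epoch, $F = \{x_0,\dots,x_{N-1}\}$, are embedded with window length
$K = 256$ (2 s) into the $L \times K$ Hankel trajectory matrix, $L = N - K
+ 1 = 128$:

$$\mathbf{X} = \begin{pmatrix}
x_0 & x_1 & \cdots & x_{K-1}\\
x_1 & x_2 & \cdots & x_K\\
\vdots & & \ddots & \vdots\\
x_{L-1} & x_L & \cdots & x_{N-1}
\end{pmatrix},\qquad
\mathbf{X} = \mathbf{U}\boldsymbol{\Sigma}\mathbf{V}^{\mathsf T}
 = \sum_{i=1}^{d} \sigma_i\,\mathbf{u}_i \mathbf{v}_i^{\mathsf T},
\quad d = \min(L, K) = 128 .$$

The 384th sample is carried but not embedded: embedding all 384 samples
would give a $129 \times 256$ matrix, and the $128 \times 256$ shape is
the anchor of the whole downstream structure (128 eigentriples, a
six-group split of ranks 1–128). Each $(\sigma_i, \mathbf{u}_i,
\mathbf{v}_i)$ is an *eigentriple*; the relative contribution of triple
$i$ is $\sigma_i^2 / \sum_k \sigma_k^2$. Eigentriples are grouped by rank
into six sets — 1–2, 3–4, 5–7, 8–10, 11–20, 21–128 — chosen so the
strongest components are resolved finely and the weak tail is pooled. Each
group's matrix $\sum_{i \in g}\sigma_i \mathbf{u}_i\mathbf{v}_i^{\mathsf
T}$ is mapped back to a series by **diagonal averaging** (Hankelization):
entry $s$ of the output is the mean of the anti-diagonal $p + q = s$. We
use the standard averaging weights $\min(s, L, K, L{+}K{-}s)$; the
printed piecewise formulas for this operation in the SSA literature vary
in their case boundaries, and the unambiguous specification is the fixed
point property — diagonal averaging of the Hankel matrix of any series
must return that series exactly, which this choice satisfies (and the test
suite enforces at $10^{-12}$). The six reconstructed series are the
**intrinsic mode functions** (IMFs); by SVD completeness and linearity of
the averaging they sum to the embedded epoch to machine precision.

Two implementation notes. The SVD sign ambiguity is fixed by making the
largest-magnitude entry of each $\mathbf{u}_i$ non-negative, so repeated
runs are bit-identical. Group reconstruction uses the identity that the
anti-diagonal sums of $\mathbf{u}\mathbf{v}^{\mathsf T}$ are the linear
convolution $\mathbf{u} * \mathbf{v}$, evaluated for all 128 eigentriples
at once by FFT; `reconstruct_group()` keeps the direct matrix definition
and the tests assert both paths agree to $10^{-12}$.

An all-zero epoch is flagged `degenerate` (zero IMFs, undefined
contributions) rather than erroring an entire recording.

## Hilbert features

For each IMF the analytic signal $z(t) = \mathrm{imf}(t) +
i\,H[\mathrm{imf}](t)$ is formed by the FFT method; the instantaneous
amplitude is $a(t) = |z(t)|$ and the instantaneous frequency (IF) is the
derivative of the unwrapped phase, taken by central differences (one-sided
at the ends). Samples whose envelope lies below $10^{-6}\max a$ — where
phase is numerically meaningless — and IF estimates outside $[0,
f_s/2]$ are treated as missing, never clamped. Two scalars summarise an
IMF per epoch:

* **CF** (center frequency, Hz): the $a^2$-weighted mean IF, i.e. the
  first moment of the marginal Hilbert spectrum $h(\omega) = \int
  H(\omega, t)\,dt$ in the small-bin limit. An unweighted mean is
  available (`weighted = FALSE`) but the power-weighted form is the
  default because it is the natural "average of the Hilbert spectrum".
* **TP** (total power, dB): $10\log_{10}$ of the *mean* $a^2$ per sample
  (µV²). The mean, rather than the sum, makes TP invariant to epoch
  length.

Hilbert edge effects on 3-s epochs can bias CF slightly; a
`trim_seconds` option excludes edge samples from the scalar features
(default 0).

## Feature tables and regression

Per-epoch features (CF1–CF6, TP1–TP6) are aggregated onto an 8-s grid —
the cadence of processed depth-of-anesthesia parameters — by the median of
the epochs whose centers fall in each cell; BIS is matched at the nearest
timestamp within half a grid step. Per-recording tables are collapsed
cellwise by the median into one cohort table, and BIS is regressed on the
12 parameters by OLS with intercept on complete cases (rows with missing
cells are dropped and counted). A rank-deficient design raises an error
naming the offending columns rather than silently dropping them.
Significance selection is single-pass — fit the full model, keep
parameters with $p < 0.05$, refit once — not stepwise, so the reduced
model is directly comparable to the full one. All fit metrics ($R^2$,
MAE, RMSE) are in-sample; the package deliberately reports the same
quantities an anesthesiology reader expects from a regression table.

The default regression target is the cohort-median table. Phase summaries
split the analyzed span into three equal phases (200 s each over 600 s):
per parameter and phase the median, IQR, and percent change relative to
the maintenance median ($100\,(m_{\mathrm{ph}} -
m_{\mathrm{maint}})/|m_{\mathrm{maint}}|$; the absolute-value denominator
keeps the sign interpretable when medians cross zero), with a
Kruskal–Wallis omnibus test and Bonferroni-corrected pairwise
Mann–Whitney tests. Phases with fewer than three rows flag their tests as
insufficient instead of producing fragile p-values.

## The synthetic cohort

`generate_recording()` produces a 600-s, 128-Hz recording built from
components whose phase schedule (three 200-s phases, 10-s linear
cross-fades) emulates emergence from sevoflurane-like anesthesia:

| component | maintenance | transition | emergence | rationale |
|---|---|---|---|---|
| delta oscillation (peak µV @ Hz) | 25 @ 1.2 | 12 @ 1.0 | 4 @ 0.8 | slow-wave dominance fades |
| theta-range broadband, 4–12 Hz (µV RMS) | 4 | 2.5 | 1 | diffuse mid-band power of the anesthetized brain |
| alpha spindles (peak µV @ Hz, /min) | 12 @ 11, 40 | 6 @ 10, 25 | 1.5 @ 10, 8 | spindle loss toward awakening |
| beta band noise 15–30 Hz (µV RMS) | 0.5 | 4 | 7 | fast activity rises before emergence |
| 1/f² background (µV RMS) | 3 | 3 | 3 | steep spectral decay of frontal EEG |

plus a 0.3 µV RMS white measurement floor (the noise level of clinical
acquisition hardware). Spindles are Hann-windowed bursts drawn from an
inhomogeneous Poisson process. Each band amplitude additionally carries an
independent slow lognormal modulation (sd 0.25 log-units, 20-s correlation
time) emulating the minute-scale waxing and waning of anesthetic depth.
This within-phase variability matters statistically: without it the twelve
features co-vary along a single latent trajectory and no individual
coefficient could ever reach significance, making the selection stage
vacuous.

Two generator choices deserve justification. The background is $1/f^2$ in
power, not $1/f$: anesthetized frontal EEG decays steeply, and a flatter
background would park the residual-group IMF's center frequency near
$f_s/4$ in every phase, which is not what anesthetic EEG looks like. The
explicit theta component fills the 4–12 Hz band that lies between the
slow waves and the spindles; anesthetic EEG is theta-rich, and without it
the mid-rank IMFs have no physiological counterpart.

The programmed **BIS-like index** is a clipped affine function of the
log10 per-second band powers of the generated signal (delta 0.5–4, alpha
8–13, beta 15–30 Hz): intercept 78, weights −14 (delta), −10 (alpha),
+20 (beta), Gaussian noise sd 2, clipped to $[0, 100]$. The weights were
chosen once, from amplitude arithmetic, so the index runs from ≈ 40 in
maintenance to ≈ 90–95 at emergence — the clinically expected course —
and rises monotonically in expectation. Because the index is affine in
*band* powers while the pipeline regresses on *IMF* features, the
regression recovery test is non-trivial (the model must learn the
band-to-mode correspondence) yet well-posed. Cohorts jitter every phase
amplitude and frequency by ±10% per recording through one seed tree
(base seed → per-recording seeds → per-component draws), so a fixed base
seed reproduces the cohort exactly.

What the generator does *not* emulate: burst suppression, EMG/EOG and
electrode artifacts, per-patient spectral idiosyncrasies beyond amplitude
jitter, and any pharmacokinetic coupling between bands. Tests passing on
this cohort therefore demonstrate that the pipeline recovers programmed
spectral structure and a programmed index under realistic noise — not
that it reproduces any particular clinical dataset.

## Numerical and design choices

* **Epoch/embedding off-by-one** — epochs carry 384 samples; embedding
  uses the first 383 so the trajectory matrix is exactly 128 × 256. Both
  lengths are configurable (`epoching_config()`).
* **Grouping for $d \ne 128$** — ranges are clipped; ranges above $d$
  become empty groups yielding zero IMFs, keeping the six-IMF contract.
* **IF estimator** — unwrap + central difference; out-of-range samples
  missing, not clamped; amplitude floor $10^{-6}$ relative.
* **Marginal-spectrum bins** are centered on multiples of the bin width
  so round-frequency tones do not straddle an edge.
* **Complete-case regression** with counts of dropped rows logged;
  collinearity is an error, not a silent repair.
* **Determinism** — fixed SVD signs, seed trees for all synthesis, no
  parallelism; byte-identical TSVs on rerun.

## Problem sizes used by the test and acceptance runs

Unit tests run on seconds-long recordings. The end-to-end checks use the
full default conditions — a 10-recording, 600-s cohort (≈ 3,000 epoch
decompositions) for the regression fit, and 50 single-recording seeds
restricted to the maintenance and emergence phases (≈ 10,000 epochs) for
the CF6 phase-contrast rate. On one CPU the whole acceptance computation
takes about four minutes.

## Known limitations

* SSA here is the basic (Broomhead–King) variant: no sequential SSA, no
  w-correlation-based automatic grouping, no forecasting.
* CF of very-low-frequency IMFs is ill-conditioned on 3-s epochs (a 0.5 Hz
  component completes 1.5 cycles per epoch), which is visible as wide IQRs
  for the slowest modes — a property shared by the method itself.
* The regression is in-sample OLS by design; cross-validated or
  regularized fits are out of scope.
* The BIS is a proprietary index; the package treats it (and the
  synthetic stand-in) purely as a numeric regression target.
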