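---
title: "Estimating the unitary response and discharge latency distribution from eCAPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the unitary response and discharge latency distribution from eCAPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecapdeconv)
```

## The model

An electrically evoked compound action potential (eCAP), recorded through a
cochlear implant after a single stimulation pulse, is the superposition of
many near-identical single-fiber contributions. Under the classical unitary
response assumption, every auditory-nerve fiber contributes the same
stereotyped waveform — the unitary response, UR — and the eCAP is the
convolution of that UR with the compound discharge latency distribution
(CDLD), the function that weights fiber firings over time:

$$\mathrm{eCAP}(t) = \int \mathrm{CDLD}(\tau)\,\mathrm{UR}(t - \tau)\,d\tau.$$

The CDLD is non-negative by construction; its shape encodes firing
synchronicity and its area scales with the number of excited fibers. Neither
factor of the convolution is observable on its own in humans, so both are
parameterized and estimated from recordings.

**Unitary response.** A biphasic, phase-switched pulse with five parameters:
for $t < t_0$ the negative phase $(U_N, \sigma_N)$ applies, for
$t \ge t_0$ the positive phase $(U_P, \sigma_P)$, and

$$\mathrm{UR}(t) = U\,e^{1/2}\,\frac{t - t_0}{\sigma}
  \exp\!\left(-\frac{(t - t_0)^2}{2\sigma^2}\right).$$

The $e^{1/2}$ factor peak-normalizes the lobes: the trough is exactly $-U_N$
at $t_0 - \sigma_N$ and the peak exactly $+U_P$ at $t_0 + \sigma_P$, so the
amplitude parameters read directly in µV. This resolves the dimensional
ambiguity of writing the two lobes as $U\sigma(t-t_0)\exp(\cdot)$: the
amplitude constants are defined as peak magnitudes, so the implementation
makes them exactly that.

**CDLD.** A mixture of $K$ unit-peak Gaussian components,

$$\mathrm{CDLD}(t) = \sum_{k=1}^{K} \alpha_k
  \exp\!\left(-\frac{(t - \mu_k)^2}{2\sigma_k^2}\right),
  \qquad \alpha_k \ge 0,$$

with $K = 2$ as the default ("early" and "late" neural response groups).
Components are unit-peak rather than unit-area because the $\alpha_k$ are
defined as peak amplitudes. Components are always reported sorted by
ascending $\mu$ (ties by ascending $\sigma$), which removes the
label-switching ambiguity of mixtures.

## The two-step procedure

Direct spectral division (`fft_deconvolve()`) solves the convolution equation
exactly on clean data but amplifies noise in the nearly-empty bins of the UR
spectrum: on realistic recordings the recovered CDLD acquires negative phases
and high-frequency ripple, which contradicts what a latency distribution is.
The historical remedy — a 2.5 kHz zero-phase low-pass plus an upward shift
(`strahl_postprocess()`) — is included for comparison, but it alters the very
quantity of interest.

The deconvolution fitting-error minimization routine (DMR) avoids the inverse
problem altogether: it predicts the eCAP by forward convolution and minimizes
$\lVert \mathrm{eCAP}_c - \mathrm{eCAP}_p \rVert_2$ over the model parameters
within box bounds, in two steps.

* **Step one** (`fit_step_one()`): all 11 parameters (5 UR + 6 CDLD, $K=2$)
  are free. Run over a series of eCAPs, each fit yields a UR estimate; their
  parameterwise arithmetic mean (`average_urs()`) is the representative UR.
  Because UR and CDLD interact freely here (a scale factor can move between
  $\alpha_k$ and $U_N, U_P$ without changing the product — the forward model
  is bilinear), step-one CDLDs are not interpretable and are discarded.
* **Step two** (`fit_step_two()`): the UR is frozen (either the step-one
  average or the published human UR, $U_N = 0.155$ µV, $\sigma_N = 0.038$ ms,
  $U_P = 0.022$ µV, $\sigma_P = 0.155$ ms, $t_0 = -0.128$ ms) and only the
  $3K$ CDLD parameters move. All temporal structure is thereby driven into
  the CDLD, and the $\alpha_k \ge 0$ domain keeps it non-negative without any
  post-processing. A fit with NRMSE fit index above 0.9 is classified
  accurate.

The default box domains and starting values are the published ones (see
`dmr_bounds_step1()` and `dmr_bounds_step2()`); note the step-one and
step-two latency domains differ ([0.04, 1.3] vs [0.15, 1.35] ms) and both are
kept as printed for their respective steps. The goodness-of-fit measure is
the fit-index form of the normalized root-mean-square error,
$1 - \lVert r \rVert / \lVert \mathrm{eCAP}_c - \overline{\mathrm{eCAP}_c}
\rVert$, so 1 is perfect and "good" fits sit near 1 rather than near 0.

## Preprocessing

Two operations precede any fit (`preprocess_waveforms()`):

* **Baseline correction** — the mean amplitude of the tail (all samples at or
  beyond `tail_start`, default 1.5 ms, where neural activity has died out) is
  subtracted from the whole waveform. Idempotent.
* **Signal extension** — 50 samples are added to each end, linearly
  extrapolated to baseline, reaching zero one virtual sample beyond the added
  block. This pushes the edge distortion inherent in finite-length discrete
  convolution outside the analysis window. The original samples are preserved
  exactly.

## Numerical choices

* **Convolution scaling.** The discrete convolution sum is multiplied by the
  sampling interval (`conv_scale = "dt"`), making the forward model a
  grid-resolution-independent approximation of the convolution integral
  (halving `dt` changes the output by well under 0.5% of peak). The raw sum
  (`"none"`) is available for compatibility with conventions that absorb the
  interval into the amplitudes; fit indices are unaffected by the choice, the
  absolute scale of the fitted $\alpha_k$ is not comparable across
  conventions. The UR is evaluated internally on
  $[t_0 - 6\sigma_N,\, t_0 + 6\sigma_P]$; truncated tails contribute less
  than $10^{-8}$ of peak.
* **Bounded least squares.** The box constraints are enforced through the
  smooth interior reparameterization $p = \ell + (u-\ell)\sin^2\theta$ under
  which plain Levenberg–Marquardt iterates stay strictly inside the box. This
  matters: projecting iterates onto the box can park a width parameter
  exactly at its $\sigma = 0$ bound, where the component's gradient vanishes
  and the fit stalls in a spurious solution. Tolerances default to $10^{-10}$
  (function and parameter), 500 iterations.
* **Refits for hard waveforms.** If the solution is not accurate (fit index
  $\le 0.9$), the same starting values are handed to two bound-constrained
  quasi-Newton solvers (`nlminb`, then `L-BFGS-B`), and if still inadequate,
  a small set of data-informed alternative starts is tried: over a coarse
  latency/width grid the optimal amplitudes are obtained by a linear solve
  (the forward model is linear in $\alpha$), and the few best,
  mutually-distinct candidates re-seed the optimizer. This is a deterministic
  analogue of the manual start re-tuning the original procedure prescribes
  for waveforms that fit poorly, and it only ever runs when the default
  single-start fit is inadequate. The lowest-SSE solution wins; the starting
  point itself is always a candidate, so a fit can never end worse than it
  began.
* **Model-order sweep.** `model_order_sweep()` fits $K$ in `k_range`
  (default 1–6) with nested initialization: the fit for $K+1$ starts at the
  $K$-component optimum plus a new component at the default latency/width
  start but with $\alpha = 0$. Starting the richer model exactly at its
  predecessor's optimum makes the residual norm provably non-increasing in
  $K$ (the optimizer never accepts an uphill step); a nonzero $\alpha$ start
  would forfeit that guarantee.
* **Degenerate widths.** The printed domains allow $\sigma = 0$; the
  evaluator treats it as the point-mass limit (zero everywhere off the exact
  latency), and a component that converges to $\alpha = 0$ is retained, as
  the inclusive bound implies.

## The synthetic generator

No public eCAP corpus exists, so validation runs on seeded synthetic
recordings (`synthetic_spec()`, `simulate_batch()`) with the generative
structure the model assumes: known UR (the published human UR by default)
convolved with a known two-component CDLD on a 0–2.2 ms window sampled at
5 µs (441 samples), plus a constant baseline offset and additive white
Gaussian noise with SD equal to 1% of the waveform's peak amplitude.

Component parameters are drawn uniformly — $\alpha \in [0.05, 0.35]$,
$\mu \in [0.3, 0.9]$ ms, $\sigma \in [0.03, 0.15]$ ms — with rejection until
three structural constraints hold:

* latencies separated by at least twice the summed widths (clearly bimodal);
* every amplitude at least 0.05 (no vanishing components);
* $\mu_k - 3\sigma_k \ge 0.25$ ms, so no discharge mass falls before the
  recording window opens.

The ranges are deliberately narrower than the step-two *fit* domains, which
are search bounds calibrated for clinical heterogeneity, not a description of
plausible firing patterns: widths below ~0.03 ms would be narrower than the
UR itself and latencies outside ~0.3–0.9 ms would push the N1 trough out of
the window or response energy into the baseline tail. The onset constraint
mirrors the flat-tail-after-1.5-ms structure of recorded data at the other
end of the window: fibers do not fire before the stimulus, so a recorded eCAP
is flat at the start of its window. Without it, draws would place response
energy before $t = 0$ where a recording cannot see it; the window-truncated
waveform then disagrees with the forward model at the leading extension, and
richer CDLD models spuriously "improve" by fitting that artifact.

What the generator does **not** emulate: stimulus-artifact residue,
alternating-polarity paradigms, correlated or non-Gaussian recording noise
(telemetry noise spectra are not characterized in the source material),
across-fiber UR variability, and amplitude growth with stimulus level.
Passing validation on these synthetics therefore demonstrates that the
estimation machinery is correct and well-conditioned under the model's own
assumptions — not that those assumptions hold for any particular clinical
recording.

## Validation at desk scale

`run_validation_suite()` (also driven by `scripts/acceptance.R`) simulates
100 waveforms, preprocesses and step-two-fits all of them, and sweeps the
model order on the first 20: problem sizes chosen so the whole suite runs in
well under a minute on one core. It reports the percentage of accurate fits
(index > 0.9), the mean residual-norm reduction from $K=1$ to $K=2$, and the
mean further reduction from $K=2$ to $K=6$. The package's tests additionally
verify noiseless parameter recovery (median absolute relative error below 1%
over 50 draws), the FFT round trip (exact inversion on clean data, negative
phases under 2% noise), bound compliance, CDLD non-negativity, nested-sweep
monotonicity, and the convolution operator against the closed-form
Gaussian–Gaussian convolution.

```{r example, eval = FALSE}
spec <- synthetic_spec(n_waveforms = 5, seed = 1)
batch <- simulate_batch(spec)
fits <- fit_batch(batch$waveforms, ur = published_human_ur())
glance(fits)
autoplot(fits$fit[[1]])
```

## Known limitations

* The absolute scale of fitted $\alpha_k$ depends on the convolution-scaling
  convention and the sampling interval of the data; compare amplitudes only
  within one convention.
* The unitary response is phenomenological; no claim is made about biophysics
  of single fibers, and the constancy of the UR across subjects, electrodes
  and levels is an assumption of the method, not a finding of this package.
* Waveforms whose morphology the fixed UR cannot express (small N1 with large
  P1) fit poorly by design; the fit index flags them rather than forcing a
  CDLD interpretation.
* The optimizer solves a non-convex problem; the refit ladder makes failures
  rare on data that satisfies the model, but a fit index near or below 0.9
  should always be inspected before the CDLD is interpreted.
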