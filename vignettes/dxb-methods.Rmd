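---
title: "Diffracted X-ray blinking: model, estimator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffracted X-ray blinking: model, estimator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

Diffracted X-ray blinking (DXB) watches a Debye–Scherrer ring with a
photon-counting area detector under monochromatic X-rays. A crystallite (or
a gold nanocrystal label attached to a molecule) diffracts only while its
orientation satisfies the Bragg condition; rotational diffusion and lattice
("d-space") fluctuation carry it in and out of that condition, so each
detector pixel on the ring sees its photon count blink. The temporal
statistics of that blinking encode the motion.

For one pixel's count series $I(t)$ sampled at the frame interval
$\Delta t$, the package computes the normalized intensity autocorrelation

$$\mathrm{ACF}(\tau) \;=\; \frac{\langle I(t)\, I(t+\tau)\rangle_t}{\langle I(t)\rangle_t^{\,2}},
\qquad \tau = \Delta t, 2\Delta t, \dots$$

with a single global mean in the denominator, so the estimator is exactly
invariant under rescaling of $I$ (flat-field factors, gain) and under time
reversal (the set of lag-$m$ products does not change when the series is
reversed). Each curve is fitted by nonlinear least squares to

$$\mathrm{ACF}(t) = A\,e^{-\Gamma t} + y, \qquad A, \Gamma, y > 0,$$

and a fit is *accepted* iff $A>0$, $y>0$, $\Gamma>0$ and the residual
score is below 1.0. For a two-state blinking process with entry rate
$k_\mathrm{on}$ and exit rate $k_\mathrm{off}$, theory gives
$\Gamma = k_\mathrm{on}+k_\mathrm{off}$ exactly (the telegraph
autocovariance decays at the sum of the rates), which is what makes the
simulator an oracle for the whole chain. The median accepted $\Gamma$,
together with a configured rotational displacement $\Phi_\theta$ (pm),
yields the rotational diffusion coefficient

$$D_R = \frac{\Gamma\,\Phi_\theta^2}{4} \quad [\mathrm{pm^2/s}].$$

## Rising ACFs and time reversal

On real rings roughly half the pixels show ACFs that *rise* with lag —
pixels dominated by spots entering rather than leaving the Bragg
condition. The literal estimator cannot distinguish the two by reversal
(it is reversal-invariant), so the package implements the entry-process
analysis as a model choice: pixels whose ACF slope over the first quarter
of lags is positive are fitted with the saturating growth model
$y - A e^{-\Gamma t}$, which shares the decay constant with the mirrored
decay curve. A pixel receives exactly one direction; an exactly zero
slope classifies as decay. Note that the *population* ACF of a stationary
process always decays from its zero-lag maximum; rising single-pixel
curves arise from finite records and non-stationary entry events, so in
long stationary simulations the growth class is populated mainly by
noise-dominated pixels. This is a real difference between the simulator
and experimental data and is deliberate: it keeps the ground truth exact.

## The synthetic movie generator

`sim_config()` + `render_movie()` produce movies whose defaults are the
study conditions used throughout the tests:

* 2000 frames at `frame_interval = 0.05` s (exposure 42 ms is carried as
  metadata only; counts represent the full interval — the ~16% dead time
  rescales intensity uniformly and the ACF normalization cancels it);
* spots of `psf_size = 3` pixels (uniform square kernel, matching the
  observed ~3×3-pixel spot extent; flux `on_intensity` is conserved over
  the footprint);
* two-state telegraph kinetics sampled with the *exact* two-state
  propagator over each interval, so rates are unbiased at 50 ms (no
  small-step Euler error), with the initial state drawn from the
  stationary distribution;
* an alternative angular-diffusion mode: orientation angles perform a
  reflected Brownian walk in a window several acceptance-half-widths
  wide, giving a uniform stationary density and hence a predictable
  on-fraction `halfwidth / range`;
* Poisson photon noise per pixel per frame on top of
  `background = 2` counts/pixel/frame, with per-spot peak flux
  `on_intensity = 45` photons/frame (5 per footprint pixel). These count
  levels describe a weak laboratory source on a photon-counting detector:
  single-photon-sensitive pixels, low diffuse background, spots tens of
  photons per frame;
* spots placed by seeded rejection sampling on an annulus (`sim_ring()`,
  optionally with finite radial width), at least `psf_size` apart in
  Chebyshev distance so no two footprints overlap and every trace is
  single-spot;
* optional linear drift (`drift_slope` counts/frame at spot pixels) to
  exercise detrending.

What the generator does **not** emulate: overlapping spots, azimuthal
spot motion along the ring, polarization/solid-angle envelopes, detector
gain dispersion, charge sharing, or radiation damage. Passing tests
therefore validate the estimator and pipeline logic under ideal blinking
statistics, not detector systematics.

## Signal-free pixels, binning, and two rejection guards

With 3×3-pixel spots, analysis of a sparse ring inevitably includes ROI
pixels with no signal at all. A pure Poisson pixel has a flat *population*
ACF, but the *sample* estimator has smooth, correlated fluctuations across
lags, and a three-parameter exponential fitted to such a curve can satisfy
the four acceptance conditions with an arbitrary decay constant — the
printed conditions test positivity and residual magnitude, not amplitude
*significance*. Two numerical guards keep this in check without altering
the acceptance rule itself:

* a converged rate faster than one frame interval
  ($\Gamma > 1/\Delta t$) is rejected as *degenerate*: the exponential has
  decayed away by the first fitted lag, so amplitude and rate are not
  jointly identifiable from the curve (the same logic that treats a
  converged amplitude below $10^{-6}$ as violating $A>0$);
* noise fits whose initial amplitude estimate is non-positive fail at the
  constraint boundary and are rejected as non-converged.

These guards remove roughly half of the spurious noise-pixel fits; the
remainder contribute decay constants of the same order as real signals
and dilute, but no longer dominate, the ensemble on sparse data.

What about binning? Binning to the spot extent raises per-pixel counts
and is the right call when individual pixels are photon-starved — the
reason the original method bins. But on well-exposed sparse data it has a
cost this package's simulations expose: spots land at arbitrary positions
relative to the bin grid, so many binned pixels contain only a corner of
a spot, and those weak partial-spot pixels fit with decay constants
biased upward (we measured about +80% at amplitude-to-noise ratios
around 2). Unbinned, every footprint pixel of a spot has the same
amplitude and no such stratum exists. The packaged end-to-end study
therefore analyzes unbinned pixels on ring-matched annuli; choose
`bin_size` for real data by per-pixel SNR, and prefer unbinned analysis
whenever single-pixel amplitudes are already well above the ACF noise
floor.

## Numerical choices

* **Lag range.** `max_lag_fraction = 0.25`: lags run to N/4 frames. Long
  lags average few products and degrade the fit; the choice is
  configurable and stated in every resolved configuration.
* **Residual rule.** The acceptance threshold (< 1.0) applies to the
  *sum* of squared residuals over all fitted lags — the strictest reading
  of the printed criterion; a mean-squared alternative is available as
  `residual_rule = "mean"`.
* **Fit initialization.** $y_0$ = mean of the last quartile of the curve,
  $A_0$ = first value − $y_0$ (reflected for growth), $\Gamma_0$ =
  reciprocal of the half-crossing lag with fallback $1/\tau_{\max}$;
  optimizer bounds place all three parameters above $10^{-12}$, and a
  converged amplitude below $10^{-6}$ counts as violating $A>0$ (a flat
  curve has no dynamics). Optimizer failure yields a rejected fit with
  the reason recorded, never an error.
* **Detrending.** Ordinary least squares line removed and the original
  mean added back, so the normalization is untouched; policy `auto`
  removes a trend only when the slope differs from zero at the 5% level
  (the original description removes trends "when present" without giving
  a criterion, so the package makes the test explicit). Because blinking
  traces are strongly autocorrelated, the slope test uses an AR(1)
  effective-sample-size correction: a naive i.i.d. t test fires on about
  90% of stationary blinking traces, and detrending a stationary trace
  strips low-frequency signal and inflates the fitted decay constant.
* **ACF computation.** Lagged-product sums are computed by FFT
  autocorrelation; for integer count traces the sums are integers and are
  rounded back exactly, so the estimator's scale- and reversal-invariance
  hold bit-exactly on count data.
* **Binning.** Non-overlapping blocks, remainder rows/columns/frames
  dropped rather than zero-padded (padding would bias the ACF
  normalization); a binned pixel is valid only if all constituents are
  valid.
* **Ring geometry.** Flat-detector small-solid-angle mapping
  $r = L\tan 2\theta$; no polarization or solid-angle correction, since
  static per-pixel factors cancel in the normalization.
* **Ensemble statistics.** Two summaries coexist because both are in
  use: the Cauchy–Lorentz mode (histogram or MLE fit) for distribution
  plots, and the median — which enters $D_R$. Histogram bins follow
  Freedman–Diaconis (recorded in the output); below 20 accepted pixels
  the Lorentz fit is skipped and only boxplot statistics are reported.
  Rank-sum comparisons use exact enumeration up to n = 20 without ties,
  otherwise the tie-corrected normal approximation without continuity
  correction (identical samples then give p = 1 exactly).
* **$\Phi_\theta$.** A required configuration input, in pm. The printed
  values of the source experiments are not reproducible from the printed
  geometry by a simple pixel-subtense formula (the derivation lives in
  prior work), so the package never computes it; a clearly-labeled
  diagnostic pixel-subtense estimate can be logged for sanity only.
  Relatedly, the gold (111) table row (2θ = 38.24°, d = 2.32 Å at
  λ = 1.54 Å) is not Bragg-consistent (the closed form gives 2.35 Å);
  the package documents rather than "fixes" this, and validates
  `bragg_d()` against the self-consistent rows.

## Problem sizes used in the shipped studies

The packaged end-to-end study simulates 320-spot, 2000-frame movies
(two superposed thin rings on a 340×340 detector — more independent
blinking trajectories than a single ring can hold without footprint
overlap) at rate sums 0.3/0.6/1.2 s⁻¹ and requires the accepted-pixel
median Γ to land within 15% of the truth, unbinned, on ring-matched
annuli. The frame-splitting study uses two conditions (0.4 vs
0.6 s⁻¹, 60 spots, 160×160 detector), splits 2000 frames into 2/4/10
segments, and tracks how the rank-sum p-value between conditions grows as
the per-segment record shortens — reproducing the qualitative observation
that distinguishing conditions needs long records. These sizes were chosen
as the smallest that leave the statistical conclusions clearly resolved.

## Known limitations

* $\Gamma$ recovery is validated for rate sums within roughly
  [0.2, 2] s⁻¹ at 50 ms framing; far outside that window the decay is
  either unresolved within the lag range or aliased by the frame rate.
* The acceptance conditions do not test amplitude *significance*; on
  sparse unbinned data, noise pixels can enter the ensemble (see the
  binning section).
* The growth-model branch assumes the rising curve saturates within the
  lag window; strongly non-stationary pixels (a spot appearing once,
  late) are not modeled.
* No multiple-testing correction is applied to pairwise condition
  comparisons by default (raw pairwise significance is reported, matching
  the original analyses); `holm = TRUE` enables it.
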