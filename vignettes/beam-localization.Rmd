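---
title: "Beam-based angular localization: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-based angular localization: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonarbeam)
```

`sonarbeam` asks a narrowly posed question: if the only directional element
of a bat's sonar system were its **emission beam**, how well could the angle
of a reflector be estimated from the spectrum of a single echo, and how do
call design and mouth gape shape that limit? This vignette is the package's
own account of the model, the conventions it had to fix, and what the
numbers do and do not mean.

## The observation model

A call is synthesized as a sum of `M` linear FM down-sweeps. Harmonic `p`
sweeps from `f_{0,p}` down to its terminal frequency over the duration `T`
(3 ms by default), as `cos(2π(f_{0,p} t + ½ m_p t²))` with the sweep rate
`m_p` fixed by the endpoints. The amplitude envelope is a Kaiser window with
`β = 4`, which gives the smooth, convex amplitude spectrum peaking between
the terminal and start frequencies that is typical of vespertilionid calls.
Every waveform is rescaled to unit total energy, so all comparisons between
designs are at equal total power.

The mouth is a baffled circular piston of radius `a`. Its far-field pressure
gain at off-axis angle `θ` and frequency `f` is

```
h(θ, f) = | 2 J₁(x) / x |,   x = (2π f / c) · a · sin θ,   c = 343 m/s,
```

with `h = 1` on axis. The pattern depends on its inputs only through
`a·f·sin θ / c`; this *aperture–frequency duality* (doubling the radius is
equivalent to doubling all frequencies) is exact for the gain and is verified
to 1 % for the end-to-end localization metrics in the test suite. `a` is the
piston **radius**; "mouth gape" in the interface always refers to this
radius.

The beam template table `g(θ)` holds, for every angle on a grid, the
amplitude spectrum of the call as emitted toward `θ`. Two synthesis routes
are provided:

* `time_varying` (default): each harmonic is attenuated sample-by-sample by
  `h(θ, f_p(t))` at its instantaneous frequency, and the spectrum is the FFT
  magnitude of the resulting waveform. This is the faithful model of a swept
  source through a frequency-dependent filter.
* `per_band`: the on-axis spectrum is multiplied by `h(θ, f)` at each band
  centre. It is several times faster and, for single-harmonic 3 ms sweeps,
  agrees with the default within 0.5 dB per band at small angles for all
  bands within 20 dB of the row peak. Near piston nulls the two differ by
  construction — the swept synthesis smears energy across the null, the
  per-band route goes to zero exactly — so per-band agreement is stated, and
  tested, away from nulls. The median per-band difference stays below 0.2 dB
  even at large angles.

An echo from angle `θ₀` is observed as `y = g(θ₀) + n` with independent
zero-mean Gaussian noise of standard deviation `σ` in every band, taken
literally: noise lives in the spectral domain and negative noisy amplitudes
are retained. Optionally the observation is an order-4 gamma-tone channel
energy vector instead (below).

## Conventions the model had to fix

Several quantities in this problem have no single community convention; the
package fixes each one explicitly.

**Frequency bands.** Spectra live on the positive-frequency bins of an
8192-point FFT at 500 kHz sampling (≈61 Hz spacing), restricted to the bands
within 25 dB of the on-axis spectral peak — the same support convention used
to define a species' bandwidth. For the 130→40 kHz call this keeps ~1470
bands spanning roughly 39–132 kHz.

**SNR.** `sigma_from_snr()` defines SNR as total on-axis echo energy over
total noise energy across the K active bands:
`SNR_dB = 10·log₁₀(‖g(0)‖² / (K σ²))`. This makes the nominal SNR invariant
to how finely the FFT subdivides the spectrum. Other definitions (per-band
peak SNR, time-domain broadband SNR, or a dB-domain noise model) rescale σ
by large factors; consequently *absolute* bound values at a nominal SNR are
convention-dependent and should be read comparatively. Under this convention
the 40 dB CRLB for the M. emarginatus configuration bottoms out near
0.009°; under harsher per-band conventions the same curve shifts up by one
to two orders of magnitude, with its shape — and every comparative statement
in the package — unchanged. The CRLB's exact `×10` shift per 20 dB of SNR is
tested to 1e-9.

**Estimator.** For unknown echo amplitude and per-band Gaussian noise, the
ML estimate of angle maximizes `(g(θ)ᵀy)² / ‖g(θ)‖²`; the package reports
the equivalent normalized form `L̄(θ) = (g(θ)ᵀy)²/(‖g(θ)‖²‖y‖²)`, which is
scale-invariant in both arguments and bounded by 1 (Cauchy–Schwarz), with
equality only at self-match. Ties break toward the smaller angle, and an
all-flat curve is flagged (`flat_peak`) rather than silently resolved.
`ml_estimate(..., refine = TRUE)` polishes the grid argmax by continuously
maximizing the same statistic against per-band templates within one grid
step. The refinement exists because the default 0.05° grid quantizes
estimates: at 60 dB SNR the CRLB is of order 0.001°, far below the grid
step, and a pure grid argmax would be quantization-limited. With refinement
the Monte Carlo RMSE matches the bound within 15 % at 5–60° off axis
(200 trials), and stays above the `CRLB·(1 − 3/√n)` efficiency floor at 40
and 60 dB.

**Peak width.** Accuracy is scored by the curvature of the noiseless
self-correlation at its peak, `PW(θ₀) = |∂²L̄/∂θ²|^(-1/2)` by central
differences on the fine grid (the absolute value makes the expression
well-defined at a maximum, where the second derivative is negative). The
curvature definition is deliberate: at small angles the main lobe often does
not drop to half height on the broadside side, so threshold widths would be
undefined exactly where the curves are most interesting. At `θ₀ = 0` the
beam's even symmetry makes the curvature vanish; the angle is flagged
`flat_peak` and reported as infinite width, and flagged angles are excluded
from averages.

**PSLR.** Ambiguity is `10·log₁₀(peak / largest side lobe)` on `L̄`, where
the main lobe is the contiguous region around the peak down to the first
local minimum on each side and side lobes are local maxima outside it
(including a rising domain edge). `10·log₁₀` on the squared-correlation
curve is the package's convention; since `L̄` is a squared quantity, readers
who think in amplitude correlation should halve the dB values.

**Report angles and averages.** Profile metrics are evaluated at 1°–89° in
1° steps and averaged uniformly, excluding flagged angles. The averaging
window is a genuine free choice with a visible effect on the absolute means
(restricting to 1°–60° lowers the mean PW of broad-beamed configurations by
tens of percent); the package fixes one convention and keeps it everywhere.

**Mouth gape.** The species presets carry the radius of the normally opened
mouth; the "full gape" condition multiplies it by 2 (`gape_factor`,
adjustable). With the signal fixed, doubling the radius roughly halves the
angular scale of the beam pattern (exactly so in `sin θ`), so peak widths
shrink by a factor approaching 2 at small angles and the mean PW ratio comes
out between 2.3 and 2.9 over the 1°–89° window — more than 2 because the
fixed averaging window weights the (strongly shrunken) wide-peak region of
the half-gape profile.

**Harmonic weights.** The five-component call modelled after a
*Rhinopoma microphyllum* approach call (components 2–6 of a 16→12 kHz
fundamental, jointly covering 24–96 kHz; the near-silent fundamental is
omitted) uses equal power per component, as no weighting convention is
better motivated; weights are a `signal_spec` field and can be changed.

## The gamma-tone front end

`build_gammatone_bank()` places order-4 gamma-tone filters at
`f_ck = 5703·2^(k/13.5)` Hz — 13.5 channels per octave — with each filter's
equivalent rectangular bandwidth set to 13.5 % of its centre frequency. For
an order-n gamma-tone with envelope `t^{n-1} e^{-2πbt}`, the ERB equals
`b·∫(1+u²)^{-n} du` (≈0.98175·b at n = 4), fixing `b_k ≈ 1.0186·ERB_k`. The
printed decay rule `b = 0.74·f_c` found in parts of the auditory literature
is dimensionally inconsistent with a 13.5 % bandwidth, so the bandwidth
statement wins. Channel outputs are RMS values of the filtered waveform
(computed exactly in the frequency domain via Parseval); white-noise channel
RMS therefore grows as the square root of channel bandwidth, which the tests
check against the analytic ERB. Re-expressing the beam table through the
bank (`gammatone_table()`) and re-running the estimator reproduces the
expected qualitative picture: accuracy within a factor of 2 of the
full-spectrum front end below 20° off axis, and a PSLR that is lower at
every report angle (coarser spectral sampling fills in the notches that
distinguish neighbouring angles). Noise-free gamma-tone comparisons are used
for these checks; noisy gamma-tone runs add spectral-domain noise to the
channel energies, consistent with the band-noise model.

## What the simulations emulate — and what they do not

The framework models the *emitted beam only*. Deliberately outside the
model: the bat's head-related transfer function (pinna/head filtering),
binaural cues (ILD/ITD), the reflector's own frequency response, atmospheric
attenuation, range estimation from pulse–echo delay, and Doppler. Real
echoes carry all of these, so passing tests here demonstrate properties of
the beam-information channel, not absolute behavioural performance. Because
the beam is rotationally symmetric about the mouth axis, a single echo
constrains only the off-axis cone angle (a circular ambiguity); azimuth and
elevation separation needs the excluded cues. Likewise, the Gaussian
band-noise generator is a deliberately minimal receiver model: it has no
cochlear compression, no detection threshold and no correlation across
bands, so Monte Carlo error rates quantify estimation-theoretic limits
rather than psychophysical thresholds.

Within its scope, the model's comparative statements are robust and are
pinned by property-style tests: localization accuracy improves with
bandwidth and with terminal frequency; ambiguity (PSLR) improves with
bandwidth but *worsens* with terminal frequency — the accuracy–ambiguity
trade-off; and widening the mouth gape improves accuracy at no ambiguity
cost, because it raises the normalized terminal frequency `a/λ₁` and the
effective bandwidth `a/λ₂ − a/λ₁` together. Among the five species presets,
M. nattereri's ultrawideband call yields the best accuracy and the highest
PSLR in both gape conditions.

## Numerical choices and degenerate inputs

* Angle grid 0°–90° at 0.05°; curvature and beam derivatives use central
  differences at this step. Curvatures below 1e-12 deg⁻² flag `flat_peak`.
* `piston_gain` switches to the series `1 − x²/8` below `x = 1e-6` to avoid
  0/0 at the axis; elsewhere it uses R's `besselJ`.
* The CRLB at `θ = 0` is reported as infinite with a `zero_information`
  flag: by even symmetry the angle derivative of the template vanishes
  exactly on axis.
* Observations at angles off the grid are rejected, never snapped; zero-norm
  observations and zero template rows are rejected.
* Monte Carlo substreams are derived per (angle, SNR) cell from the master
  seed, so results are bit-reproducible and cells are independent;
  `.Random.seed` is restored after each draw so package calls do not disturb
  the caller's RNG state.
* Band selection rejects thresholds that keep no bands; `normalize_curves`
  rejects non-positive values.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
keep the full suite in a few minutes on one core: fine-grid tables
(1801 × ~1470), Monte Carlo at 200 trials per (angle, SNR) cell on 5°-spaced
angles, Fisher-information oracles at 30 000 draws on a 10× thinned band
set, and coarse 0.25°–0.5° grids where only structure (not curvature) is
asserted. Production analyses can raise trial counts and grid resolution
freely; all computations are vectorized over angles and bands.

## Known limitations

* Absolute peak-width and PSLR values depend on the correlation-domain,
  averaging-window and dB conventions above. Comparable published summaries
  of this system exist whose per-species mean peak widths (mouth normally
  open) run ~0.7× the values produced here with gape ratios near 1.8; an
  extensive convention search (linear vs power vs log-spectral correlation,
  centred vs uncentred statistics, curvature step, averaging weights and
  windows) could not reproduce those absolute cell values and ratios
  simultaneously under the piston model, so the package treats absolute
  metric levels as convention-bound and its own conventions as definitive
  for reproducibility. All *directional* results are insensitive to these
  choices.
* The piston is an idealization: real bat beams deviate from circular
  symmetry, and the baffle assumption is questionable at low `ka`.
* The CRLB is a local bound; it ignores side-lobe-induced gross errors,
  which is why Monte Carlo RMSE detaches from it as SNR falls.
* Bayesian threshold-region bounds (Ziv–Zakai, Weiss–Weinstein) would
  characterize the low-SNR regime better than the CRLB and are left as
  future work.
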