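# sonarbeam

Quantifies the angular information carried by the **emission beam** of an
echolocating bat, and how a bat could tune that information by changing its
call design or its mouth gape.

Most FM bats emit sound through the open mouth, which acts approximately as a
circular piston: the beam is directional, and more so at high frequencies.
A reflector at off-axis angle θ is therefore insonified by an
angle-specific spectrum, and the spectrum of its echo carries information
about θ — a monaural localization cue that exists only in active sensing.
`sonarbeam` is for sensory ecologists and bioacousticians who want to ask,
quantitatively: *how much* angular information does a given call/gape
combination put into the world, and what does widening the mouth or changing
the sweep buy?

## The model

- **Call synthesis.** An FM call is a sum of linear down-sweeps
  `x_p(t) = cos(2π(f₀,p t + ½ mₚ t²))` under a Kaiser envelope (β = 4),
  3 ms by default, normalized to unit total energy so that designs are
  compared at equal power.
- **Beam.** A baffled circular piston of radius *a*: the pressure gain at
  angle θ and frequency *f* is `|2 J₁(x)/x|` with `x = (2πf/c)·a·sin θ`.
  The angle × band matrix of emitted amplitude spectra `g(θ)` is the beam
  template table.
- **Observation.** An echo is the amplitude spectrum `y = g(θ₀) + n`, with
  independent Gaussian noise per frequency band; optionally the spectra are
  re-expressed as channel energies of an order-4 gamma-tone filter bank
  (centre frequencies `5703·2^(k/13.5)` Hz, ERB = 13.5 % of centre).
- **Estimation.** The maximum-likelihood angle for an echo of unknown
  amplitude is the peak of the squared normalized correlation
  `L̄(θ) = (g(θ)ᵀy)² / (‖g(θ)‖²‖y‖²)`.
- **Scores.** Accuracy = correlation main-lobe width
  `PW(θ) = |∂²L̄/∂θ²|^(-1/2)` at the peak; ambiguity = peak-to-side-lobe
  ratio (dB). Absolute limits come from the Cramér–Rao lower bound under the
  per-band Gaussian model and from seeded Monte Carlo RMSE of the ML
  estimator.

## Worked example

```r
library(sonarbeam)

# An M. emarginatus-like call: 130 -> 40 kHz linear FM sweep, 3 ms,
# emitted through a 6.3 mm piston aperture
spec  <- signal_spec(130e3, 40e3)
mouth <- emitter(6.3e-3)
beam  <- angle_spectrum_table(spec, mouth)
beam
#> <angle_spectrum_table> 1801 angles x 1470 bands (time_varying mode), radius 6.30 mm

# A noiseless echo from a reflector at 25 degrees
echo  <- make_observation(beam, 25, noise_spec(Inf, 0))
curve <- correlation_curve(echo, beam)
curve
#> <correlation_curve> peak 1 at 25.00 deg
ambiguity <- pslr(curve)
round(c(pslr_db = as.numeric(ambiguity), side_lobe_deg = attr(ambiguity, "side_angle")), 2)
#>       pslr_db side_lobe_deg
#>          0.77         50.90

# Accuracy and ambiguity across angles
profile <- metrics_profile(beam)
profile
#> <localization_metrics> 89 angles; mean PW 25.54 deg, mean PSLR 0.80 dB

# Theoretical accuracy limit at 40 dB SNR (total-energy convention)
noise <- noise_spec(40, sigma_from_snr(40, beam))
bound <- crlb_curve(beam, noise, angles = 1:80)
bound
#> <crlb_curve> SNR 40 dB (unknown amplitude); best 0.009144 deg at 17.0 deg

# What does opening the mouth buy? (radius doubled, signal fixed)
gape_experiment(species_presets()[2, ])
#>          species pw_half_gape pw_full_gape pslr_half_gape pslr_full_gape
#> 1 M. emarginatus     23.13652     9.046734      0.8321257      0.8950718
```

Reading the numbers: the echo from 25° is identified exactly (correlation 1
at 25°), but a secondary correlation maximum at ~51° sits only 0.77 dB below
the peak — under heavy noise the estimator can jump there, which is the
accuracy–ambiguity trade-off in miniature. The CRLB says that at 40 dB SNR
(energy convention, see the vignette) the beam alone could support
sub-degree localization, best around 17° off axis, where the beam spectrum
changes fastest with angle. Doubling the M. emarginatus mouth radius narrows
the mean correlation peak from ~23° to ~9° without lowering the mean PSLR.

A command-line interface wraps the same functions
(`inst/scripts/sonarbeam`): subcommands `beam`, `correlate`, `metrics`,
`crlb`, `mc`, `species`, `sweep`, `map`, `fixtures`, with CSV/JSON output and
a metadata sidecar per run. Example:

```sh
Rscript inst/scripts/sonarbeam species --gape-factor 2 --out species.csv
Rscript inst/scripts/sonarbeam crlb --radius-mm 6.3 --f-start-khz 130 \
    --f-terminal-khz 40 --snr-db 40 --out crlb.csv
```

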