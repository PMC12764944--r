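---
title: "Mapping linear dichroism and tissue alignment from polarization-resolved photoacoustic images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping linear dichroism and tissue alignment from polarization-resolved photoacoustic images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichropam)
```

## The measurement and its model

Dichroism-sensitive photoacoustic microscopy images a specimen at several
incident linear-polarization angles. Fibrous structures absorb
anisotropically, so the photoacoustic amplitude at polarization
$\theta$ follows the two-parameter linear-dichroism model this package
assumes throughout:

$$p_\theta(x,y) = a(x,y) + b(x,y)\cos^2\!\big(\theta - \varphi(x,y)\big),$$

where $a \ge 0$ is the isotropic absorption amplitude, $b \ge 0$ the
dichroic (orientation-dependent) amplitude and $\varphi$ the local fibre
axis. This is the unique two-parameter form that the four-angle Stokes
inversion reproduces exactly, which is why the phantom generator uses it
as its forward model: with

$$I = p_0 + p_{90}, \quad Q = p_0 - p_{90}, \quad U = p_{45} - p_{135},$$

one gets $I = 2a + b$, $Q = b\cos 2\varphi$, $U = b\sin 2\varphi$, hence

$$\mathrm{DoLD} = \frac{\sqrt{Q^2 + U^2}}{I} = \frac{b}{2a+b}, \qquad
\mathrm{AoLD} = \tfrac{1}{2}\operatorname{atan2}(U, Q) = \varphi.$$

Two conventions deserve comment. First, we use the quadrant-aware
`atan2(U, Q)` rather than a plain arctangent of $U/Q$: the plain form
cannot separate $\varphi$ from $\varphi + 90^\circ$ and is undefined at
$Q = 0$, while `atan2` reproduces $\varphi$ exactly on the forward model.
Second, all orientation angles are degrees, counter-clockwise from the
image $+x$ axis, reduced to the axial range $[-90^\circ, 90^\circ)$ —
fibre axes are undirected, so $\varphi$ and $\varphi + 180^\circ$ are the
same axis.

## From A-lines to the $p_\theta$ images

Each scan position yields a time-resolved A-line. Its amplitude is taken
as the magnitude of the analytic signal (FFT half-spectrum doubling) — a
phase-invariant envelope, so the result does not depend on the carrier
phase or on sign conventions of the transducer chain. The
maximum-amplitude projection (MAP) is the per-pixel maximum of this
envelope over time; it is invariant to time shifts, which is why per-pixel
depth jitter in the phantom leaves the MAP unchanged. On
Gaussian-modulated pulses the projected amplitude matches the generating
envelope peak to well under 1% at the default sampling (30 MHz carrier,
60% fractional bandwidth, 250 MHz sampling); the residual comes from
sampling the envelope on the time grid.

Before the Stokes step, each state's MAP is divided by that state's laser
fluence (`fluence_normalize()`). Fluence units are arbitrary — only the
per-state ratios matter — and the phantom's multiplicative drift
$g_\theta$ is removed exactly when the recorded fluence equals the drift.
No bandpass pre-filtering is applied by default; the phantoms are
broadband-clean, and a hardware chain typically band-limits before
digitization.

## Validity flags rather than silent masking

`dichroism_map()` reports per-pixel flags: `low_signal` where
$I$ falls below a threshold, `undefined_angle` where $Q = U = 0$ (an
isotropic pixel has no axis), and `model_inconsistent` where
$\mathrm{DoLD} > 1$, which the two-parameter model cannot produce — such
values are retained, not clamped, because they diagnose noise or model
violation. The default threshold is $5\times$ the median-absolute-
deviation spread of $I$ (`auto_min_signal()`), a deliberately conservative
separation of specimen from background for background-dominated fields;
it is a free parameter, and any quantitative comparison between images
should state it.

## The independent estimator

`dense_fit_oracle()` fits $p_\theta = c_0 + c_1\cos 2\theta + c_2\sin
2\theta$ per pixel by least squares over any $K \ge 3$ angles spanning at
least $90^\circ$ and converts to $(a, b, \varphi)$. It shares no code
path with the Stokes formulas, yet on noiseless canonical four-angle
stacks the two agree exactly; the test suite uses this equivalence, plus
37-angle parameter recovery, as the main correctness oracle for the
mapping step.

## Axial circular statistics

All orientation statistics operate on doubled angles
$\alpha = 2\theta$ and map back, the standard treatment of undirected
axes. The resultant vector length $R = |\sum w e^{i\alpha}/\sum w|$ is the
alignment-uniformity summary; the mean axis is $\tfrac12\arg(\cdot)$.
Weighting is unweighted by default; amplitude- and DoLD-weighted variants
are offered because pooling choices differ between laboratories, and the
choice is recorded in the output.

The 95% confidence interval for the mean axis defaults to a seeded
percentile bootstrap on the doubled-angle mean (1000 replicates): it is
valid at moderate $n$ without distributional assumptions. A large-sample
("fisher") circular standard error is available where determinism without
a seed is preferred (it is the default inside `roi_summary()` for that
reason). Coverage of the bootstrap interval is checked by simulation in
the test suite: for axial von Mises samples with concentration
$\kappa = 4$ at $n = 200$, empirical coverage over 500 seeded replicates
falls in the low-to-mid 90s, consistent with the nominal 95%.

Von Mises sampling itself uses the Best–Fisher (1979) rejection method
(no installed package provides it); its correctness is checked against
the closed-form expectation $E[R] \to I_1(\kappa)/I_0(\kappa)$ at large
$n$. Polar histograms default to 18 bins of $10^\circ$ — fine enough to
show structure at the pixel counts of typical regions of interest, coarse
enough not to be noise-limited.

## What the phantom generator emulates — and what it does not

`phantom_spec()`/`make_stack()` generate four-angle stacks from the
forward model with (i) a spatially varying orientation field, (ii)
per-state multiplicative fluence drift (a scalar per state, matching
photodiode-style per-state power monitoring), and (iii) additive Gaussian
amplitude noise clipped at zero. The noise model is a stand-in: the noise
statistics of real photoacoustic envelope amplitudes are not
characterised here, and envelope detection of noisy band-limited signals
is closer to Rician at low SNR. Defaults (`iso_map = 1`,
`dichroic_map = 1`, `noise_sigma = 0`) give the maximally simple phantom;
study-like phantoms in the tests use $b/a \approx 0.8$, noise 2–5% of the
isotropic amplitude, and fluence drift within ±10%.

`make_pin_field()` emulates the geometry of a tissue anchored on pins:
tangent (circumferential) orientations near each pin, relaxing to a
longitudinal axis between them. Pin influence decays as
$e^{-d/\ell}$ with `blend_length` $\ell$; the longitudinal component has
a fixed small weight in the doubled-angle blend, so the field is
longitudinal wherever the nearest pin is more than a few blend lengths
away. This is a geometric caricature — it reproduces the
uniformity-gradient phenomenology (lower $R$ near pins, higher at the
centre), not any mechanical model of matrix remodelling.

Passing tests on these phantoms therefore demonstrates correctness of the
*analysis* under the stated model, not robustness to real-tissue effects
(speckle, depth-dependent fluence, partial-volume mixing of fibre
populations, registration error between states). The one robustness
property that is tested is monotonicity: the circular RMSE of AoLD
decreases with SNR under additive noise.

## Activation mapping choices

Voltage-dye movies are normalized per pixel to $F/F_0$ with the 10th
percentile as the default baseline (robust when a pixel's rest period is
short; a first-$k$-frames mode is available). Activation defaults to the
50% upstroke crossing with linear interpolation between frames — at
100 fps this resolves well below one 10 ms frame on clean upstrokes — with
maximum-derivative timing (3-frame smoothed, parabolic sub-frame
refinement) as the alternative; the two agree within a frame on noiseless
sigmoidal upstrokes. Pixels whose upstroke amplitude is below `min_amp`
(default 0.05 in $F/F_0$ units) are reported as NaN rather than given
meaningless times. The synthetic wave generator places a quiescent lead
time before the transit so every pixel has a resting segment, as a
triggered recording would.

## Numerical and design notes

* Problem sizes in the tests and the acceptance script are chosen for
  desk-scale runs: $48^2$–$96^2$-pixel phantoms, $10^4$–$10^5$-draw
  circular-statistics checks, 500-replicate coverage simulations.
* Result maps are written as uncompressed float32 multi-page TIFF with a
  JSON sidecar (angles, fluence, pixel pitch). The codec is part of the
  package because no available R TIFF writer stores arbitrary float
  samples losslessly; it is cross-checked against an independent Python
  TIFF implementation in the test suite. Invalid pixels are NaN by
  convention.
* Stacks with states other than the canonical $\{0, 45, 90, 135\}$ are
  rejected by the Stokes step rather than coerced — the Stokes differences
  are defined only for those states; arbitrary angle sets go through
  `dense_fit_oracle()`.
* Sidecar angles are reduced modulo $180^\circ$; pages whose angles
  differ by $180^\circ$ are averaged under the axial-equivalent angle.
* All randomness (phantom noise, jitter, bootstrap, von Mises draws) is
  seeded, and seeded generation restores the caller's RNG state; the
  bundled demo config reproduces its outputs byte for byte.
* Ties and degenerate inputs: $R = 0$ has no mean axis (NaN, and the CI
  refuses); empty regions of interest yield an $n = 0$ record, not an
  error; a constant image yields an empty orientation sample.

## Known limitations

No acoustic propagation, transducer response, or optical diffraction is
modelled; lateral resolution can only be emulated by pre-blurring the
phantom maps. The gradient comparator implements the structure tensor —
the standard robust estimator of the gradient-orientation class — not any
specific commercial package's formulation. Circular dichroism,
birefringence (phase retardation) and Mueller-matrix polarimetry are out
of scope, as are conduction-velocity vector fields and arrhythmia
analysis on the optical-mapping side.
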