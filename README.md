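# dichropam

Analysis toolkit for **dichroism-sensitive photoacoustic microscopy
(DS-PAM)** of fibrous tissue. Fibrous proteins (collagen, fibronectin,
actin) absorb mid-infrared light anisotropically: absorption — and hence
the photoacoustic amplitude — peaks when the incident polarization aligns
with the fibre axis. Imaging the same field of view at four incident
polarization angles therefore encodes both how strongly oriented the local
matrix is and along which axis it runs, without any labelling. `dichropam`
implements the full computational chain for such data, from raw per-pixel
A-line signals to tissue-level alignment statistics, together with a
synthetic fibrous-phantom generator that provides ground truth for every
step. It is aimed at researchers analysing engineered-tissue or histology
sections with polarization-resolved photoacoustic (or comparable
polarimetric) imaging.

## The model

The per-state amplitude of a dichroic fibrous sample follows an
isotropic-plus-Malus-law model,

    p_theta(x, y) = a(x, y) + b(x, y) * cos^2(theta - phi(x, y)),

with `a` the isotropic and `b` the dichroic absorption amplitude and `phi`
the local fibre axis. From the four canonical states the Stokes parameters

    I = p_0 + p_90,   Q = p_0 - p_90,   U = p_45 - p_135

invert this model exactly:

    DoLD = sqrt(Q^2 + U^2) / I  =  b / (2a + b)     (degree of linear dichroism)
    AoLD = (1/2) atan2(U, Q)    =  phi              (orientation angle, degrees)

AoLD is an axial quantity (period 180°, reported in [−90°, 90°)), so all
downstream statistics work on doubled angles: the resultant vector length
`R = |mean(exp(2i*theta))|` is the alignment-uniformity readout (1 =
perfectly aligned, 0 = no preferred axis), with mean axis, bootstrap 95%
confidence intervals, circular SDs and polar histograms alongside.

The package also provides the two companion analyses used to corroborate
DS-PAM findings: structure-tensor orientation estimation for fluorescence
micrographs, and optical-mapping analysis of voltage-dye movies (F/F₀
normalization, single-cycle extraction, per-pixel activation times).

## Worked example

A phantom mimicking a pin-anchored engineered-tissue section:
circumferential fibres near two anchoring pins, longitudinal fibres under
tension between them, with per-state fluence drift and amplitude noise.

```r
library(dichropam)

field <- make_pin_field(96, 64, list(c(12, 32), c(84, 32)), blend_length = 8)
ph <- make_stack(phantom_spec(96, 64, orientation_field = field,
                              iso_map = 1, dichroic_map = 0.8,
                              noise_sigma = 0.02,
                              fluence_factors = c(1, 1.08, 0.95, 1.02),
                              seed = 7))
res <- dichroism_map(fluence_normalize(ph$stack))
glance(res)
#> # A tibble: 1 x 7
#>   n_pixels pct_valid mean_dold sd_dold mean_aold_deg resultant_length min_signal
#>      <int>     <dbl>     <dbl>   <dbl>         <dbl>            <dbl>      <dbl>
#> 1     6144       100     0.286  0.0110        0.0118            0.865      0.141

rois <- list(left_pin = outer(1:64, 1:96, function(y, x) x <= 24),
             centre   = outer(1:64, 1:96, function(y, x) x > 36 & x <= 60))
roi_summary(res, rois)
#> # A tibble: 2 x 9
#>   region   n_pixels mean_dold sd_dold mean_aold_deg sd_aold_deg resultant_length ...
#> 1 left_pin     1536     0.286  0.0107        0.0132       21.1             0.762
#> 2 centre       1536     0.286  0.0112       -0.0250        1.78            0.998
```

`mean_dold` ≈ 0.286 recovers the phantom's `b/(2a+b) = 0.8/2.8`, and the
resultant length separates the disordered pin region (R = 0.76) from the
aligned centre (R = 0.998) — the alignment gradient such tissues show
between anchor and midline. `autoplot(res, "aold")` renders the
orientation map; `polar_histogram()` + `autoplot()` give the polar
distribution.

A command-line front end wraps the same functions:

```sh
exec/dichropam run --config inst/extdata/demo_config.yaml
exec/dichropam dichroism --stack stack.tif --out results/
```

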