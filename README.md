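# glintloc

Horseshoe bats (Rhinolophidae) hunt fluttering insects with long,
narrowband constant-frequency (CF) calls of roughly 75 kHz and 50 ms.  A
narrowband call carries no spectral localization cues, so these bats
localize echoes differently from broadband (FM) bats: they sweep their
pinnae through an oblique arc during echo reception, which imprints a
direction-dependent binaural amplitude modulation on the received echo.
Fluttering prey adds *glints* — brief, Doppler-shifted, amplitude-stable
echo components, one dominant glint per wingbeat.  A bat that reads the
self-induced amplitude modulation only at the dominant-glint times gets a
*sampled* version of its localization cue (as few as 1–10 samples per
call, set by the insect's flutter rate) but in exchange enjoys a much
lower amplitude-noise level, because dominant-glint amplitudes are far
more stable than the rest of the echo.

`glintloc` implements the ideal-observer simulation that quantifies this
trade-off, for users in computational neuroethology and sensory-systems
modelling.  It measures how much direction information survives glint
sampling, as a function of flutter rate, echo strength and noise level.

## Model

Localization is cast as Bayesian template matching over a discrete
hypothesis grid of directions \(\theta\) on the frontal hemisphere.  For
each direction, the *template* \(T_\theta\) is the expected received
level (dB) at the left and right ear across pinna-stroke positions —
emission gain plus the rigidly rotated ear gain, normalized to zero mean
so that the unknown echo strength \(A\) carries all absolute level.  A
measurement sampled at the \(k\) dominant-glint times per ear is

\[ s = \max\{\,0,\; T_\theta + A + n\,\}, \qquad
   n \sim \mathcal{N}(0, \Sigma), \]

where the elementwise maximum models the detection floor (0 dB, so \(A\)
reads as an SNR) and \(\Sigma\) is \(\sigma^2\) on the diagonal with
correlation \(\rho\) between simultaneous left/right samples and zeros
elsewhere.  The echo strength is a nuisance parameter with a uniform
discrete prior:

\[ p(s \mid \theta) = \frac{1}{|\mathcal{A}|} \sum_{A \in \mathcal{A}}
   \mathcal{N}\!\big(s;\ \max\{0, T_\theta + A\},\ \Sigma\big), \]

and Bayes' theorem with a uniform direction prior gives the posterior
\(p(\theta \mid s)\), whose Shannon entropy
\(H = -\sum_\theta p \log_2 p\) (bits) is the *localization entropy* —
the remaining ambiguity about the echo's origin.  Per condition the
package reports the Monte-Carlo mean of \(H\) over independent draws of
the glint-phase and the noise (20 realizations per cell by default).
Performance relative to the 200 Hz flutter baseline is summarized as

\[ P(f) = 100 \cdot
   \frac{\sum_A \big(H_{\max} - \bar H(f, A)\big)}
        {\sum_A \big(H_{\max} - \bar H(f_{\text{base}}, A)\big)},
   \qquad H_{\max} = \log_2 N_{\text{templates}}, \]

so \(P(f_{\text{base}}) = 100\%\) by construction.

Since no measured *R. rouxii* directionality is bundled, the package
generates parametric Gaussian-lobe emission/ear beams (and can load
measured or simulated directivity grids from CSV).  Absolute entropy
values therefore describe the synthetic configuration, not the real bat;
the qualitative orderings (entropy vs flutter rate, strength, noise;
sampled-glint channel vs whole-echo channel) are the reproducible
content.

## Worked example

```r
library(glintloc)

cfg <- experiment_config(grid_size = 200,
                         flutter_rates_hz = c(20, 60, 100, 200),
                         echo_strengths_db = c(10, 30, 50),
                         realizations = 10, seed = 42)
setup <- setup_experiment(cfg)
setup$templates
#> binaural_templates: 200 directions x 2 ears x 40 stroke positions
#>   dynamic range: mean 35.9 dB (sd 17.5)

res <- run_flutter_sweep(cfg, setup, channels = "low")
subset(res$differences, mode == "regular" & echo_strength_db == 30)
#>  channel    mode flutter_hz echo_strength_db mean_entropy_bits delta_vs_base_bits
#>      low regular         20               30      3.215874e+00        3.215872357
#>      low regular         60               30      1.122095e-02        0.011218997
#>      low regular        100               30      1.128770e-03        0.001126817
#>      low regular        200               30      1.953668e-06        0.000000000

performance_curve(res$surfaces[["low.regular"]], 200)
#>  flutter_hz performance_pct
#>          20        57.28031
#>          60        99.44603
#>         100        99.88771
#>         200       100.00000

run_template_diagnostics(cfg, setup)$nyquist
#>  flutter_hz samples_per_ear nyquist_cycles_per_stroke
#>          20               1                       0.5
#>          60               3                       1.5
#>         100               5                       2.5
#>         200              10                       5.0
```

Reading: at a 30 dB echo a 20 Hz flutter (a single glint per ear) leaves
about 3.2 bits of ambiguity, but from 60 Hz up the entropy is within
0.012 bits of the 200 Hz baseline — in the low-noise dominant-glint
channel, sampling costs almost nothing.  The Nyquist table shows why this
is remarkable: 5 glints per 50 ms call can only reconstruct template
modulations up to 2.5 cycles per ear stroke, well below the content of
typical templates.  Robustness comes from the low noise, not from
sampling-proof templates.

Other drivers: `run_entropy_maps()` (Lambert-projected entropy maps per
flutter rate), `run_channel_comparison()` (sampled dominant-glint channel
vs the noisier whole-echo channel), `run_tradeoff_maps()`
(sensitivity–accuracy trade-off vs echo strength).  A thin CLI wrapper
lives at `inst/scripts/glintloc-cli.R`.

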