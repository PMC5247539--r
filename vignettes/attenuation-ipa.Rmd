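---
title: "Attenuation imaging and the Index of Plaque Attenuation for IV-OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attenuation imaging and the Index of Plaque Attenuation for IV-OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octipa)
```

## The model

Intravascular OCT records, per rotation angle and pullback frame, an A-line
of backscattered intensity versus depth. In the single-scattering regime the
detected mean intensity follows

$$\langle I_d(r)\rangle = T(r)\,S(r)\,I_0\,e^{-\mu_t r},$$

with $r$ the radial distance from the catheter axis (mm), $T(r)$ the
confocal gate of the catheter optics, $S(r)$ the system sensitivity
roll-off, $I_0$ the source-side amplitude and $\mu_t$ the tissue attenuation
coefficient (mm$^{-1}$). $\mu_t$ is the quantity of interest: fibrous
tissue attenuates weakly (roughly 2–5 mm$^{-1}$), while lipid cores and
macrophage accumulations attenuate strongly (roughly 8–12 mm$^{-1}$), which
makes $\mu_t$ a tissue-type contrast.

`octipa` estimates $\mu_t$ by compensating the measured intensity for
$T(r)S(r)$ and regressing $\ln\!\big(I/TS\big)$ on $r$ by ordinary least
squares in short depth windows: the negated slope is $\mu_t$, the intercept
$\ln I_0$, and the regression $R^2$ serves as fit quality. Log-linear OLS
rather than nonlinear exponential fitting keeps the estimator convex,
deterministic and fast, and is the classical slope-of-log approach for OCT
attenuation. We fit *intensity* (not amplitude) data; amplitude-domain data
would halve the slope, so the convention matters and is fixed here.

The functional forms used for compensation are a Lorentzian confocal gate
$T(r) = \big[((r - z_f)/z_R)^2 + 1\big]^{-1}$ (focus position $z_f$,
apparent Rayleigh length $z_R$) and a Gaussian roll-off
$S(r) = \exp\!\big[-(r/r_0)^2\big]$, with $S \equiv 1$ when no roll-off
length is configured. These are standard catheter-OCT parameterisations;
if a system's calibrated curves differ, any positive compensation curve can
be emulated by adjusting the parameters, and a matched
generation/compensation pair always cancels exactly (this is tested to
$10^{-6}$ mm$^{-1}$).

## Window selection and overlap resolution

A-lines are fitted from the lumen border downward. At each window start the
candidate window lengths — default 0.6, 0.4, 0.2 mm — are tried longest
first and the first candidate whose $R^2$ reaches `min_quality` (default
0.6) is kept, falling back to the best-quality candidate when none
qualifies. Long windows average more speckle (the OLS slope standard
deviation under fully developed speckle is $(\pi/L)\sqrt{2/n}$ for window
length $L$ and $n$ samples, since $\mathrm{Var}[\ln E] = \pi^2/6$ for
unit-mean exponential speckle $E$); short windows resolve thin layers. The
longest-adequate rule prefers precision where the single-exponential model
holds and locality where it breaks.

Each window assigns its (clamped) $\mu_t$ to every sample it covers;
overlaps are resolved by keeping the higher-$R^2$ window, ties going to the
shorter (more local), then the shallower window — a deterministic rule.
Samples at or below `noise_margin` (default 2) times the recorded noise
floor are excluded from regressions, and windows with fewer than 3 usable
samples are abandoned. Estimates are clamped to 0–12 mm$^{-1}$ at storage,
mirroring the display range; perfect constant fits report $R^2 = 1$ by the
zero-residual convention (0/0 resolved in favour of acceptance).

## En-face mapping and the IPA

The en-face map takes, per valid A-line, the maximum $\mu_t$ between the
lumen border and the internal elastic lamina. "Between" is
boundary-ambiguous; both border samples are included so single-sample walls
remain representable, with sub-sample contours floored at the span start
and ceiled at the end. When the IEL is invisible (typically behind a lipid
pool) the span extends a configurable fallback depth below the lumen,
default 1 mm — behaviour in this case is a documented convention, not a
measurement.

The Index of Plaque Attenuation over a segment at threshold $x$ is
$\mathrm{IPA}_x = 1000\,N(\mu_t > x)/N_\mathrm{total}$. The inequality is
strict, taken literally from the definition. Invalid pixels (guide-wire
shadow, no estimate) are excluded from numerator *and* denominator: shadow
A-lines carry no attenuation information, and counting them as
"not above threshold" would make IPA depend on wire position. Windowed IPA
tiles the pullback with non-overlapping windows anchored at frame 0
(4 mm = 20 frames at the 0.2 mm frame pitch); the trailing partial window
is dropped rather than scored on fewer pixels.

## Lipid scores and the threshold sweep

The manual lipid score of a segment is the product of its mean lipid arc
(degrees) and lipid length (mm). Two conventions required a decision:

* **Mean arc** is averaged over lipid-*containing* frames only. Averaging
  over all frames would penalise short cores twice, once in the mean and
  once in the length factor. The alternative is available via
  `mean_over = "all_frames"`.
* **Lipid length** counts lipid-containing frames times the frame pitch,
  not the first-to-last span, consistent with reading sequential frames
  that contain lipid.

The sweep correlates per-segment $\mathrm{IPA}_x$ with the scores at each
threshold of the grid (1, 1.5, …, 12 mm$^{-1}$), skips zero-variance
thresholds, picks the argmax of Pearson's $r$ (ties to the lower, more
sensitive threshold) and fits the least-squares line of *score on IPA*
there — the regression direction is a convention ($r^2$ is symmetric, the
slope is not) chosen so the line reads as a score predictor. The $p$-value
comes from the $t$-transform of $r$ and is reported, never used for gating.

## The synthetic generator

`generate_pullback()` forward-simulates the signal model with piecewise
tissue attenuation accumulated along the beam:
$I(r) = T(r)S(r)I_0 \exp\!\big(-\!\int_\mathrm{lumen}^{r}\mu_t\,ds\big)$,
with the round-trip doubling absorbed into $\mu_t$ so the fitted and
generated coefficients agree by construction. Speckle is i.i.d. unit-mean
exponential multiplicative noise — the intensity statistics of fully
developed speckle, without the axial correlation of real OCT — and the
detection floor is a constant additive level. Above the lumen the signal is
the floor only; guide-wire shadows are floor-level arcs masked invalid.
Contours and the per-sample truth volume come from the scene geometry, so
ground truth is exact.

`generate_cohort()` draws single-plaque segments whose arc and length
follow truncated normal distributions centred on typical ex-vivo manual
reads (arc $81.98 \pm 45^\circ$, length $3.9 \pm 2.1$ mm), with lipid
$\mu_t = 10$ and background $4$ mm$^{-1}$ and a fixed lipid-free fraction
(default 8 of 23 segments, drawn as an exact count so every cohort has the
stated composition). Lipid records are derived from the scene geometry,
never from the images — they play the role of the manual reads. Segments
are 25 frames (5 mm) long so that drawn lipid lengths are not censored at
the 4-mm IPA window; IPA families are evaluated over whole segments.

What passing tests on this simulator do **not** show: robustness to
correlated speckle, catheter non-uniform rotation, blood or flush
artifacts, eccentric catheters, or segmentation error in the contours
(contours are inputs here, taken as exact). Results on clinical data
depend on those factors and on calibrated $T(r)S(r)$ curves.

## Numerical and scale choices

* Rolling window fits use exact masked moment sums (cumulative sums of
  $\{m, mr, mr^2, my, my^2, mry\}$), so excluded samples never bias the
  remaining regression; tiny negative centred sums from cancellation are
  clamped at zero.
* Default reduced simulation scale: 36 A-lines/frame, 5 µm axial pitch,
  0.2 mm frame pitch, ~200 samples/A-line; a 23-segment cohort runs in
  about 20 s, and the statistical acceptance checks use 500 A-lines per
  attenuation level with 161-sample 0.4-mm windows (the density at which
  the analytic slope standard deviation $(\pi/L)\sqrt{2/n}$ predicts
  ~0.88 mm$^{-1}$ RMSE, matching the ~1 mm$^{-1}$ accuracy expected of the
  estimator).
* Storage is 32-bit float TIFF plus JSON sidecars; a power-of-two scale
  factor keeps writes exact, so round trips are lossless at float32
  precision and pipeline reruns are byte-identical under a fixed seed.

## Limitations

Single-scattering slope fitting biases $\mu_t$ where multiple scattering or
strong specular reflections dominate; the depth-resolved (per-pixel
recursive) family of estimators is out of scope. Media segmentation is an
input, not computed. The factor-of-two amplitude/intensity convention and
the stand-in optics models are documented above; both matter when comparing
absolute $\mu_t$ values across systems.
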