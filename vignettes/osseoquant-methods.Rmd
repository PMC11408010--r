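---
title: "Methods: phantoms, models and numerical choices in osseoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantoms, models and numerical choices in osseoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osseoquant)
```

`osseoquant` quantifies bone-implant systems across four modalities:
micro-CT morphometry, XRF elemental-ratio mapping, SAXS/WAXS bone
ultrastructure, and LA-ICP-TOF-MS (LITM) elemental quantification. The ex
vivo scans such analyses are normally run on are large and not publicly
available, so the package is organised around *parameter recovery*: every
analysis chain has a synthetic-phantom generator whose ground truth is
known exactly, and the test suite asserts that the chain recovers that
truth within stated tolerances. This vignette explains the models behind
each stage, the phantoms, and the numerical decisions that were genuinely
open — with the reasoning, so a maintainer can revisit them.

## 1. Morphometry on labeled volumes

Inputs are a 3D label field (0 background, 1 bone, 2 degradation layer,
3 residual metal) at an isotropic voxel size, plus a co-registered binary
mask of the pre-implantation screw with its initial volume $V_i$ and
surface area $A_i$ measured before implantation.

* **Degradation rate** $DR = (V_i - V_r)/(A_i\,t)$ in mm/year, with the
  residual volume $V_r$ counted from the metal class. Implantation time is
  supplied in *days* and converted with 365.25 d/yr, because nominal
  "10-week" cohorts mix *per-animal* durations; per-sample days are the
  honest input.
* **Bone-to-implant contact** $BIC = 100\,A/A_d$. The "implant" here is
  the *degraded implant*: the union of residual metal and degradation
  layer, because once a corrosion shell forms it is the surface that bone
  apposes. For non-degrading implants (Ti, PEEK) pass `implant_codes = 3`.
  $A_d$ counts exposed voxel faces (6-connectivity) against any
  non-implant class; $A$ the subset abutting bone. Face counting
  overestimates smooth areas by up to $\pi/2$, but the same convention is
  used for numerator and denominator so the *ratio* is unbiased to first
  order (see Section 2 for the one subtlety this hides).
* **BV/TV** is counted inside a peri-implant shell: all voxels within
  200 µm (Euclidean) of the pre-implantation mask, minus the mask.
  Degradation-layer and metal voxels inside the shell are excluded from
  both numerator and denominator — the denominator is literally
  $V_{bone} + V_{background}$.

Surface areas, face counts and voxel counts are integer quantities; on
grids up to $20^3$ the implementation is asserted *exactly equal* to an
exhaustive triple-loop enumeration (50 random grids).

**ROI boundary correction.** The Euclidean distance transform measures
centre-to-centre distances, but the discrete screw mask samples the
continuum implant surface at voxel centres, which sit on average about a
quarter voxel inside it. A raw `distance <= margin` threshold therefore
under-dilates systematically (about $-5\%$ shell volume on sphere
oracles at margin = 5 voxels). `make_roi()` adds 0.25 voxels to the
threshold; across five independent (radius, margin) sphere cases this
brings the shell volume within about $\pm 2\%$ of the continuum value.
The correction is geometric, not fitted.

## 2. The screw phantom

`make_screw_phantom()` builds a cylinder with a *sinusoidal* thread
(default pitch 0.4 mm, the M2 pitch) rather than a true helix: the radius
profile $r(z) = a + b\sin(2\pi z/p)$ keeps every truth quantity
integrable while preserving thread-scale surface features. The screw is
eroded uniformly by the stated depth (residual metal), wrapped by a
degradation shell of stated thickness, and bone fills a stated azimuthal
fraction of the remaining space with a zero-width gap.

Truth values: $V_i$, $V_r$ by closed-form/quadrature of $\pi r(z)^2$;
$A_i$ by quadrature of $2\pi r\sqrt{1+r'^2}$; and — because bone and
background are proportioned identically at every radius and height —
$BIC_{true} = BV/TV_{true} = 100 \times$ fill fraction *exactly*.

One discretisation subtlety is worth recording. Voxel face counting
weights lateral surface elements by $|\cos\varphi| + |\sin\varphi|$
(period $\pi/2$ in azimuth $\varphi$). If bone is laid out in sectors
whose centres all fall at the *same phase* of that weight (e.g. 4 or 8
symmetric sectors), the face-count BIC converges to a *biased* limit
(~0.7 pp here) no matter how fine the voxels. The phantom therefore uses
18 sectors — a count not divisible by 4 — whose centres sample the weight
uniformly over its period, so the face-count limit equals the fill
fraction. This was found empirically when BIC error refused to shrink
under refinement, and is the reason the generator's sector count looks
arbitrary.

Refinement behaviour: measured errors at 10 → 5 → 2.5 µm are
DR 0.25 % → 0.05 % → 0.02 %, BIC 1.03 → 0.40 → 0.04 pp, BV/TV
0.57 → 0.009 → 0.02 pp. The acceptance suite asserts strict decrease over
the 10 → 5 µm refinement (ending at the 5 µm grid the tolerances are
stated for); at 2.5 µm the BV/TV error sits at the sector-edge
quantisation noise floor (~0.02 pp) where strict monotonicity of a single
realisation is no longer statistically meaningful.

## 3. XRF maps and ratio profiles

Segmentation is presence-based, as in the source workflow: degradation
where Gd is present, else bone where Ca is present, else empty. "Present"
defaults to *above the Otsu threshold* of that element's histogram
(`k * Otsu`, k configurable) since no numeric thresholds are published;
Gd takes precedence when both trigger. Optional connected-component
small-object removal cleans noise islands.

Ratios are computed **pixelwise and then averaged** (not
ratio-of-bin-sums); the alternative changes the estimand when the
denominator varies within a bin. Pixels whose denominator is at or below
a floor are excluded. Profiles bin bone pixels by Euclidean distance to
the degradation class (centre-to-centre, in µm), default 1 µm bins to
30 µm; each bin reports mean, $1.96\,SD/\sqrt{n}$ as a 95 % normal
confidence halfwidth (no definition of the published intervals exists, so
the normal approximation is declared), and $n$; empty bins are flagged,
never dropped silently. A configurable near-interface exclusion margin
(default off, 2 µm when enabled) handles the segmentation-imperfection
artefact seen within ~2 µm of real interfaces.

The XRF phantom imposes Ca/P as a function of the *centre-to-centre*
distance to a straight Gd band — deliberately the same convention the
distance map uses, so that noiseless recovery is exact and any test
failure indicts the analysis, not a half-pixel convention mismatch.
Gaussian additive noise on Ca and P models detector counts at the map
level. What the phantom does *not* emulate: curved interfaces, spectral
crosstalk between fluorescence lines, beam-energy differences between
sessions (cross-energy comparisons must be excluded by the caller), and
absorption effects. A green profile-recovery test therefore establishes
the binning/CI machinery, not XRF physics.

Group comparisons (`compare_ratio_groups()`) run Welch's t-test on
*per-sample mean* ratios — the sample, not the pixel, is the experimental
unit. Zero-variance degeneracies are answered explicitly (equal means →
$t=0, p=1$) and flagged.

## 4. Scattering

**Azimuthal integration** maps pixel radius to
$q = (4\pi/\lambda)\sin(\tfrac12\arctan(r\,p/L))$ and averages unmasked
pixels per q-bin (sum mode conserves counts exactly). No polarisation or
solid-angle corrections are applied. Intensities are divided by the
upstream monitor value. On images up to $64^2$ the binning is asserted
exactly equal to a per-pixel brute-force loop.

**Stack-of-cards platelet thickness.** $T = 4Q/(\pi P)$, with
$P = \lim_{q\to\infty} I q^4$ and $Q = \int_0^\infty I q^2\,dq$. From a
finite pattern, $P$ is the mean of $Iq^4$ over the plateau
($q \ge$ `porod_qmin`, default 4 nm⁻¹), guarded by a relative-drift check
that errors when the Porod regime was not reached. $Q$ is assembled from
three pieces: a low-q closure (fit $Iq^2 \approx c_0 + c_2 q^2$ over the
knee window — the integrand is even and smooth at 0 — integrated
analytically to $q_{min}$), the trapezoidal integral over the data, and
the analytic tail $P/q_{max}$. The published description ("fitting the
Kratky plot") fixes none of this, so the extrapolation scheme is this
package's choice; both windows are configurable, and a truncation test
asserts the tail keeps $T$ within 3 % when $q_{max}$ shrinks by 20 %.

The SAXS phantom uses
$I(q) = A e^{-q^2 R_g^2/3} + (P/q^4)(1 - e^{-q^2 R_g^2/3})$ with
$R_g = T/2$ and $A$ solved *in closed form* from the requirement
$4Q/(\pi P) = T$ — both integrals
($\int q^2 e^{-aq^2} = \sqrt{\pi}/(4a^{3/2})$,
$\int (1-e^{-aq^2})/q^2 = \sqrt{\pi a}$) are analytic, so the truth is
defined through the identity itself rather than through any fitting. The
$R_g = T/2$ convention is arbitrary within the solvability constraint
$T > (4/\sqrt{3\pi}) R_g$ and is declared, not fitted. Multiplicative
Gaussian noise models counting statistics. $T$ must lie in [0.5, 20] nm
(model validity). The generator does not emulate a real bone pattern's
structure factor, orientation anisotropy, or background from embedding
medium — recovery tests validate the invariant/Porod bookkeeping only.

**WAXS.** The phantom frame carries a Debye-Scherrer ring centred at
$q_0 = 2\pi/d$ whose Gaussian radial FWHM is $2\pi K/\tau$ — the exact
q-space form of Scherrer broadening, since
$dq/d(2\theta) = (2\pi/\lambda)\cos\theta$ cancels the $\cos\theta$ in
$\beta = K\lambda/(\tau\cos\theta)$. The analysis fits Gaussian + linear
baseline by least squares (`nls`, `optim` fallback), converts
$FWHM_q \to \beta$, and applies Bragg and Scherrer with $K = 1$ and *no*
instrumental-width deconvolution by default (none is described for the
source instrument); a subtract-in-quadrature option exists. Round trips
recover $d$ within 0.5 % and $\tau$ within 10 % at SNR ≥ 20 — the $\tau$
tolerance absorbs pixel-sampling broadening of a few-pixel-wide ring.

## 5. LITM quantification

Calibration: ordinary least squares CPS vs ppm per element over gelatin
standards (10–1000 ppm), after subtracting the gelatin-blank baseline.
Only Mg, Ca, Gd and Ti have standards; P and Fe cannot be quantified
against gelatin and pass through as CPS, flagged. The *drift* model fits
one line per standard-scan time (start / middle / end of the timeline)
and interpolates slope and intercept piecewise-linearly in acquisition
time — the minimal model consistent with the bracketing design; a 10 %/h
synthetic drift is quantified with < 2 % bias. Negative concentrations
are floored at zero with the floored-pixel count reported.

LOD is `mean + 3*sd` over a ≥ 30-pixel control area. **Thresholding
happens in signal (CPS) space**: the ppm zero-floor truncates the
baseline distribution, and with it the control-region exceedance of
mean + 3s rises from the ~0.1–0.3 % tail the definition implies to ~2 %.
Computing the LOD and the %-above-LOD on the raw channel (the LOD is an
instrument property of the channel) preserves the intended statistics;
the ppm conversion is affine, so ordering is unchanged.

Region classification mirrors the percentile rules: with per-channel
cutoffs $c$ at the 99.9th percentile (linear interpolation between order
statistics — the definition matters at 99.9 % and is fixed here), a pixel
is degradation when the implant channel (¹⁵⁵Gd or ⁴⁷Ti) is *visible* and
Ca < 0.5 c, P < 0.5 c, Fe < 0.2 c. "Visible" is published only as a
display criterion; it is operationalised as
signal ≥ f · c with **f = 0.10 by default — the single most consequential
free parameter in this module**, deliberately mandatory in configuration
and impossible to source from the text. Tail-streak artefacts (washout)
are not auto-detected; a manual exclusion mask is accepted. Interface
bands default to 0–50 / 50–150 / > 150 µm from the degradation boundary
(no published values exist). Region reports give mean, SD, *and median*
per channel (whether published per-region values are means or medians is
unstated; both are reported).

The LITM phantom renders piecewise-constant ppm rectangles through
`CPS = sensitivity · ppm · (1 + drift · t) + baseline` with Poisson
counting noise (TOF counting) and a row-major raster timeline; standards
are recorded as exact expectations since physical standard scans average
many pixels. Sensitivities and baselines are fixed plausible constants
(e.g. Gd 150 cps/ppm, baseline 20 cps); no published values exist and
nothing downstream depends on their magnitudes, only on linearity.

## 6. Noise models and defaults (the stated world)

No modality's noise statistics are published; the defaults are
assumptions, exposed as parameters:

| Stage | Model | Default level | Why |
|---|---|---|---|
| XRF | additive Gaussian per map | sd 5 on P ≈ 100 (SNR 20) | photon counting at map level |
| SAXS | multiplicative Gaussian | 5 % | relative counting error |
| WAXS frame | additive Gaussian counts | sd 50 on peak 1000 (SNR 20) | detector counts |
| LITM | Poisson on CPS | — | TOF counting |

Phantom sizes default small (volumes ≤ ~256³ equivalent, maps ≤ 512²) so
the whole suite runs on one CPU in minutes. Screw-phantom defaults
(radius 0.25 mm, one 0.4 mm pitch, erosion 30 µm, shell 40 µm, fill 0.6,
t = 0.5 y) were chosen once as a representative mid-healing geometry that
fits a 5 µm grid in memory.

## 7. Determinism and units

Every generator takes a seed, restores the caller's RNG state, and is
bit-reproducible given (parameters, seed); `run_pipeline()` writes a
manifest with per-file MD5 checksums that is identical across reruns with
the same seed. Units are fixed at I/O boundaries: µm for
pixels/voxels/distances, nm for $d$, $\tau$, $T$, nm⁻¹ for $q$, mm/year
for DR, ppm (mg/kg) for concentrations.

## 8. Known limitations

- No grayscale segmentation, image registration, or tomographic
  reconstruction: volumes arrive labeled and registered.
- The thread is sinusoidal, not helical; end-cap surfaces are not modeled
  (the phantom screw spans the grid).
- No 2D scattering anisotropy/orientation analysis; no detector flat
  field or dead-time corrections; q-calibration is reduced to one
  multiplicative scale factor.
- LITM tail streaks are an input mask, not a detection; no isotope
  interference correction; no raw TOF spectra.
- Whether the degraded-implant surface should include the cortical cut
  face, and how partial-volume voxels were originally treated, are
  unknowable from the text; faces at the domain boundary are simply not
  counted, and labels are taken as given.
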