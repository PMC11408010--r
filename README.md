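# osseoquant

Multi-modal quantification of degrading bone-implant systems in R.

Biodegradable magnesium–gadolinium (Mg-xGd) screws are designed to carry
load while bone heals and then dissolve. Judging whether that works
requires combining several imaging modalities, each with its own bespoke
quantification: micro-CT morphometry of the explant, scanning X-ray
fluorescence (XRF) of the bone next to the implant, scanning SAXS/WAXS of
the bone ultrastructure, and laser-ablation ICP-TOF-MS (LITM) elemental
imaging. `osseoquant` implements those four analysis chains as one tested,
reusable pipeline, and — because the underlying ex vivo scans of animal
tissue are not publicly available — ships a synthetic-phantom generator
with exactly known ground truth so that every stage is verifiable by
parameter recovery.

## What it computes

**Morphometry** (from a labeled volume: background / bone / degradation
layer / residual metal, plus a registered pre-implantation screw mask):

- degradation rate `DR = (V_i − V_r) / (A_i · t)` [mm/year]
- bone-to-implant contact `BIC = 100 · A / A_d` [%], counted on voxel
  faces of the degraded implant (residual metal + degradation layer)
- bone volume fraction `BV/TV = 100 · V_bone / (V_bone + V_background)`
  [%] inside a 200 µm peri-implant shell built by Euclidean dilation of
  the pre-implantation screw

**XRF**: presence-based segmentation (Gd → degradation layer, Ca → bone),
per-pixel Ca/P ratios binned by distance to the implant interface (mean ±
95 % CI per bin), degradation-layer Gd/P, Ca/P, Gd/Ca statistics, and
blood-vessel-centred profiles.

**Scattering**: azimuthal integration `q = (4π/λ) sin(atan(r·p/L)/2)`;
mineral platelet thickness from the stack-of-cards relation
`T = 4Q/(πP)` with the invariant `Q = ∫ I q² dq` and Porod constant `P`;
(002) Gaussian peak fit; Bragg's law `nλ = 2d sinθ`; Scherrer crystallite
size `τ = Kλ/(β cosθ)`.

**LITM**: gelatin-standard calibration (static, or piecewise-linear drift
between the start/middle/end standard scans), CPS→ppm conversion,
limit of detection `LOD = mean + 3s` over a control area, percentile-rule
region classification (implant channel visible at ≥ f·99.9th percentile;
Ca, P < 50 % and Fe < 20 % of their cutoffs), and per-region statistics
including %-pixels-above-LOD.

## Worked example

```r
library(osseoquant)

# a threaded screw eroded by 30 um, wrapped in a 40 um degradation shell,
# with 60 % bone apposition, voxelized at 5 um
ph <- make_screw_phantom(voxel_um = 5, erosion_depth_um = 30,
                         layer_thickness_um = 40, bone_fill_fraction = 0.6)
morphometry_report(ph$volume, ph$reference, t_days = 183)
#>           Vi       Vr volume_loss         dr     bic     bvtv   t_years
#> 1 0.06400995 0.048185  0.01582495 0.05383555 60.3233 60.01547 0.5010267
ph$truth$dr_true   # 0.05397567  -> recovered to 0.3 %
```

`dr` says the screw surface retreats at ~0.054 mm/year; `bic` that ~60 %
of the degraded implant surface touches mineralized bone; `bvtv` that
~60 % of the peri-implant shell volume is bone — all within the stated
tolerances (3 %, 2 pp, 2 pp) of the generator's analytic truth
(BIC = BV/TV = 60 exactly, by construction).

WAXS round trip at 15 keV (λ = 0.082656 nm):

```r
fr  <- make_waxs_frame(d_true_nm = 0.344, tau_true_nm = 20,
                       noise_model = list(type = "gaussian", sd = 50))
pat <- azimuthal_integrate(fr)
pf  <- fit_peak(pat, window_q = 2*pi/0.344 + c(-0.55, 0.55))
bragg_d(pf$center_q, 0.082656, input_kind = "q")   # 0.3440024 nm
cv  <- fwhm_q_to_beta(pf$fwhm_q, pf$center_q, 0.082656)
scherrer_size(cv$beta_rad, cv$theta_rad, 0.082656) # 20.0741 nm
```

End-to-end demo (all four stages on phantoms, with run manifest):

```r
run_pipeline(run_config(out_dir = "oq_out", seed = 1))
```

## Command line

An `oq` shim is installed under the package's `exec/` directory:

```sh
oq run --config cfg.json --seed 1 --out outdir
oq simulate --out phantoms --seed 2
oq morpho --labels L.tif --ref R.tif --days 61 --margin-um 200 \
          --vi-mm3 0.064 --ai-mm2 1.18
oq xrf --ca ca.tif --p p.tif --gd gd.tif --pixel-um 0.5 --bin-um 1 --max-um 30
oq saxs --pattern saxs.dat
oq waxs --pattern waxs.dat --wavelength-nm 0.082656
```

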