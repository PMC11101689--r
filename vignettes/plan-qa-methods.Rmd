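---
title: "Methods: dosimetric and geometric QA of dose-escalated plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetric and geometric QA of dose-escalated plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planqa)
```

This vignette documents the models implemented in `planqa`, the assumptions
behind them, every tunable parameter with its default and rationale, what the
synthetic data generator does and does not emulate, and the numerical
conventions that determine the package's exact outputs.

## 1. Setting and model

The package targets the dummy-run / benchmark-case stage of a multi-centre
dose-escalated radiotherapy trial for glioblastoma. A reference case is
defined by a structure set (gross tumour volume GTV, a PET-derived biological
target volume BTV, their union GTVu, nested planning target volumes, and
organs at risk) and a dose distribution with two prescription levels
delivered as a simultaneous integrated boost: a standard level (60 Gy to
PTV60) and an escalated boost (75 Gy to PTV75). Each centre's submission is
compared with the reference on three axes:

1. **Dosimetry** — DVH metrics against protocol constraints;
2. **Geometry** — contour agreement with the reference delineations;
3. **Risk** — modelled brain-radionecrosis probability of the escalated
   plan relative to the standard plan.

All computations happen on a regular voxel grid (`grid_geometry`), with
possibly anisotropic spacing in mm. Structures are boolean occupancy arrays
(`structure_mask`); dose is a numeric array in Gy (`dose_grid`); a plan is a
`plan_bundle` of both plus prescription metadata. The report layer returns
tibbles through `tidy()` / `glance()` and plots through `autoplot()`.

### 1.1 DVH metrics

`cumulative_dvh()` builds the cumulative histogram — absolute volume (cc)
receiving at least each dose level — and retains the raw sorted voxel doses.
Metrics are expressed as specs: `D98%`, `D50%`, `D2%` (dose covering a
relative volume), `D0.03cc` (dose to the hottest absolute volume, the
near-maximum used for serial OARs), `Dmean`, `Dmax`, and `V40Gy` / `V45Gy`
(volume at or above a threshold).

### 1.2 Fractionation conversion

Dose distributions planned with a different number of fractions are
converted to the equieffective dose in the reference schedule with the
linear-quadratic model, applied per voxel: find $D'$ such that

$$D'\left(1 + \frac{D'}{n_t\,\alpha/\beta}\right)
  = D\left(1 + \frac{D}{n_s\,\alpha/\beta}\right),$$

where $n_s$ is the source plan's fraction number and $n_t$ the reference
(30). The positive root of the quadratic is taken. When $n_s = n_t$ the
conversion is the identity, which is the normal case for trial plans — the
conversion exists so that plans submitted with deviating fractionation are
still comparable. Applying the correction per voxel assumes each voxel
receives its dose in equal fractions, the usual EQD-map approximation.

### 1.3 EUD and NTCP

The equivalent uniform dose over a structure with voxel doses $D_i$ is the
generalized power mean

$$\mathrm{EUD} = \left(\frac{1}{N}\sum_i D_i^{\,a}\right)^{1/a},$$

computed in a numerically stable form (doses normalised by their maximum
before exponentiation) so large $a$ does not overflow. The normal-tissue
complication probability is the logistic dose response

$$\mathrm{NTCP} = \frac{1}{1 + (TD_{50}/\mathrm{EUD})^{k}}.$$

The risk structure is the brain minus the serial OARs (brainstem, optic
chiasm, optic nerves, pituitary) and minus GTVu; `evaluate_radionecrosis_risk()`
derives this "Brain_NTCP" structure automatically when it is not already
present. Two plans are compared via

- the **NTCP ratio** $\mathrm{NTCP}_{ex}/\mathrm{NTCP}_{ref}$, and
- the **increased risk**
  $\mathrm{IR} = \ln(1-\mathrm{NTCP}_{ex})/\ln(1-\mathrm{NTCP}_{ref})$,
  the factor by which the exponent of complication-free probability grows —
  a more conservative statistic than the plain ratio when probabilities are
  not small.

### 1.4 Contour similarity

For reference mask $A$ and submission $B$:

- **Dice similarity coefficient** $\mathrm{DSC} = 2|A\cap B|/(|A|+|B|)$,
  a volumetric overlap measure; strongly size-dependent (small structures
  score low under the same millimetric error).
- **Hausdorff distance** over boundary voxels,
  $\mathrm{HD} = \max\{h(A,B),\,h(B,A)\}$ with
  $h(A,B)=\max_{a\in\partial A}\min_{b\in\partial B}\lVert a-b\rVert$;
  sensitive to single outlier protrusions.
- **HD95**: by default the maximum of the two *directed* 95th-percentile
  surface distances (type-7 quantile). A pooled variant — the 95th
  percentile of both directed distance sets concatenated — is available via
  `symmetrize = "pooled"`, since both conventions appear in the literature
  and they differ; the max-of-directed form is the default because it is the
  more common reporting choice and never smaller than the pooled one on the
  dominating side.

Boundary voxels are in-mask voxels with a face-adjacent exterior neighbour;
the grid border counts as exterior. Distances between boundary voxel
*centres* are computed exactly via a Euclidean distance transform (see
§4.2), so no sampling or approximation error enters beyond discretisation of
the surface itself.

### 1.5 Scorecards

Protocol constraints are declarative `constraint_rule`s (structure, metric
spec, comparator, per-protocol bound, optional acceptable-variation bound,
plan scope, optionally relative to the structure's prescription), loadable
from YAML or JSON with `load_constraints()`. `evaluate_constraint()`
classifies an observation as **within_protocol**, **acceptable_variation**,
or **deviation**, with inclusive bounds (a value exactly at the per-protocol
limit is within protocol); a rule whose structure is absent from the bundle
is **not_evaluable** rather than an error, because flagging a missing
structure is itself a QA finding. `evaluate_plan()` applies all rules in
scope and reports the worst class as the plan verdict. The shipped
`inst/extdata/constraints_example.yaml` is an illustrative template, not an
authoritative protocol.

## 2. Parameters, defaults, and why

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `a` (EUD exponent) | 9 | – | Large-$a$ power mean weights hot subvolumes, appropriate for late brain injury, while staying numerically benign; a standard literature value for brain necrosis. |
| `td50` | 55.5 | Gy | Dose at 50% complication probability for brain radionecrosis at conventional fractionation. |
| `slope_exponent` ($k$) | 10 | – | Logistic slope; with $TD_{50}=55.5$ this places roughly 0.15–0.5 NTCP across the 46–56 Gy EUD range typical of these plans. |
| `alpha_beta` | 2 | Gy | Late-responding normal brain tissue. |
| `target_fractions` | 30 | – | Reference fractionation of both the 60 Gy standard and 75 Gy SIB schedules. |
| `bin_width` (DVH) | 0.1 | Gy | Fine enough that binned and exact metric paths agree within a clinically negligible 0.1 Gy. |
| PTV margins | 5 / 10 / 18 | mm | GTVu→PTV75 boost margin; PTV75→PTV60ex; GTVu→PTV60 standard CTV+PTV expansion. Configurable per `phantom_config`. |
| `penumbra_sigma` | 5 | mm | Gaussian lateral falloff scale approximating a photon SIB penumbra. |
| `background_dose` | 1 | Gy | Low scattered dose inside the brain outside target falloff. |
| `noise_sd` | 0.3 | Gy | Seeded voxel noise so dose grids are not piecewise-analytic. |
| TBR segmentation threshold | 1.8 (benchmark) / 1.6 | – | BTV is thresholded at `threshold × mean background uptake`; both values supported because benchmark and routine use differ. |
| Lesion TBR | 2.5 | – | Typical amino-acid-PET tumour-to-background ratio, comfortably above either threshold. |
| `translation_sd` | 2 | mm | Inter-observer rigid displacement scale. |
| `boundary_sd`, `boundary_smoothness` | 1.5 mm, 3 voxels | | Amplitude and correlation length of boundary noise (see §3). |
| HD percentile `p` | 95 | % | Standard robust Hausdorff variant. |

All of these are arguments with validation, not constants: `radiobiology_params()`,
`phantom_config()`, `dose_model_config()`, `perturbation_profile()`.

## 3. The synthetic generator: what it emulates, what it does not

`simulate_reference_bundle()` builds a geometric head phantom: a spherical
brain (radius 70 mm), an ellipsoidal GTV, an offset ellipsoidal BTV
(emulating a PET-avid region extending beyond the morphological tumour),
GTVu = GTV ∪ BTV, and the PTV chain by millimetre-true dilation
(GTVu +5 mm → PTV75; PTV75 +10 mm → PTV60ex; GTVu +18 mm → PTV60). OARs are
analytic primitives: brainstem cylinder, optic-nerve tubes, chiasm and
pituitary spheres. The dose model places each prescription inside its target
with a Gaussian falloff $\exp(-d^2/2\sigma^2)$ of the distance-to-target $d$
outside, takes the voxelwise maximum over SIB targets, adds brain background
and seeded noise. `simulate_pet()` produces uniform brain background uptake
with a lesion at background × TBR, and `btv_from_pet()` recovers the BTV by
thresholding — closing the loop on the PET-segmentation workflow.

`generate_center_submission()` emulates inter-centre variation: each
primitive structure (except the brain) receives a rigid translation (drawn
per axis, rounded to whole voxels so masks stay on-grid) plus a smooth
correlated noise field added to its signed distance function, which is then
re-thresholded — producing realistic coherent boundary undulation rather
than voxel salt-and-pepper. Per-structure overrides (e.g. `dilate_mm` on the
GTV) emulate systematic errors such as edema inclusion. The derived
hierarchy (GTVu, PTVs) is rebuilt from the perturbed primitives, and the
dose is re-simulated on the perturbed targets, mimicking a centre that plans
on its own contours.

**Deliberately not emulated:** CT/MR appearance (no image intensities —
contours are generated directly); beam physics (no fluence, heterogeneity
corrections, or realistic dose-gradient anisotropy — the Gaussian-falloff
model gets the DVH topology right, not the physics); heterogeneous PET
texture; deformable (non-rigid, organ-specific) anatomy differences;
inter-scanner PET calibration effects; DICOM transport (bundles use NIfTI +
JSON; structures can also be rasterised from z-stacked polygon contours via
`rasterize_contours()`, with even-odd ring semantics for holes).

## 4. Numerical choices

### 4.1 DVH convention

D-at-volume metrics use **voxel-count semantics** on the exact path: the
dose received by at least $v$ cc is the $k$-th hottest voxel dose with
$k = \lceil v / v_{\mathrm{voxel}} \rceil$. This is discrete-monotone, has
no interpolation ambiguity at plateaus (a uniform 54 Gy structure has
D0.03cc exactly 54 Gy, which matters at inclusive protocol bounds), and the
binned-interpolated value provably lies in the same bin, so the two paths
agree within one bin width (0.1 Gy). Scorecards and metric tables always use
the exact path; the binned path exists for curve export and plotting.

### 4.2 Distance transform and morphology

A compiled separable lower-envelope Euclidean distance transform (squared
distances, per-axis mm weights) underpins erosion, dilation, surface
distances and dose falloff. Margins are therefore **millimetre-true and
anisotropy-correct**: a 3 mm erosion of a 10 mm sphere leaves ≈ (7/10)³ of
the volume regardless of voxel size or aspect ratio, which voxel-structuring-
element morphology does not guarantee. The same transform evaluated on the
target's boundary at the source's boundary voxels yields *exact* directed
surface distances (verified against all-pairs brute force in the tests).

### 4.3 Other conventions

- Percentiles use R's default type-7 quantile.
- Constraint bounds are inclusive; the acceptable-variation bound must be
  no stricter than the per-protocol bound (validated at rule construction).
- Structure lookup is case-insensitive; masks are uint8 in the NIfTI bundle
  and doses double-precision, so bundle round trips are bit-exact.
- All stochastic generators take explicit seeds (`withr::with_seed`), so
  every figure and table in the package's reports is reproducible from a
  seed and a config.

## 5. Problem sizes

The package default grid is 2 mm spacing on a 96³ array (≈ 19.2 cm cube),
enough to resolve the smallest OAR (pituitary, ≈ 0.3 cc) while keeping a
full simulate–perturb–score cycle under a minute. The test suite's
Monte-Carlo blocks (20 seeds × 3 perturbation scales, etc.) use a coarser
4 mm / 48³ grid purely for speed; these sizes are a package choice, and any
`grid_geometry` the inputs share is supported.

## 6. Limitations

- The NTCP model is a single-organ logistic EUD model; it does not capture
  spatial dose effects within the brain, subvolume-specific radiosensitivity,
  or clinical cofactors, and its parameters carry the usual large
  uncertainties of outcome modelling. Reported probabilities are for *plan
  comparison*, not individual prediction.
- IR and the NTCP ratio compare modelled plans on identical anatomy; they
  say nothing about tumour-control benefit of escalation.
- DSC/HD on synthetic primitives will be more optimistic than on real,
  irregular anatomy; the generator is for pipeline validation, not observer
  studies.
- The equieffective-dose conversion assumes the whole distribution is
  delivered in equal fractions per voxel and ignores repopulation and
  incomplete repair.
- No DICOM RT import: bundles use NIfTI/JSON, with a polygon rasteriser as
  the bridge from contour-based sources.
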