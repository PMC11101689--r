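# planqa

Quality-assurance tooling for multi-centre radiotherapy dose-escalation
trials: dose–volume metrics, radiobiological risk models, contour-similarity
scoring, protocol-compliance scorecards, and a synthetic phantom generator
for benchmarking the whole pipeline end to end.

## The problem

Before a multi-centre radiotherapy trial opens, participating centres
typically complete a *dummy run*: each centre contours and plans a common
benchmark case, and the coordinating centre checks that target volumes,
organ-at-risk (OAR) delineations and dose distributions comply with the
protocol. For dose-escalated glioblastoma protocols — where a biological
target volume (BTV) from amino-acid PET is boosted well beyond the standard
prescription — this QA step must quantify three things:

1. **Dosimetric compliance** — DVH metrics (D98%, D2%, D0.03 cc, Dmean,
   V40Gy, …) of each submitted plan against per-protocol and acceptable-
   variation bounds.
2. **Delineation agreement** — geometric similarity of each centre's
   contours to the reference (Dice similarity coefficient, Hausdorff
   distances).
3. **Normal-tissue risk** — how much the escalated plan raises the modelled
   radionecrosis risk of the brain relative to the standard plan.

`planqa` implements this evaluation chain on regular voxel grids, plus a
fully synthetic head-phantom generator so the chain can be exercised and
validated without any patient data.

## Core model

All volumetric inputs live on a shared regular grid (anisotropic spacing in
mm supported throughout; all morphology and distances are computed in mm,
not voxels).

**DVH metrics.** The cumulative DVH of structure *S* maps a dose level *d*
to the absolute volume of *S* receiving at least *d*. From it:
D*p*% (dose covering *p*% of the volume), D*v*cc (dose to the hottest *v*
cc), V*d*Gy (volume at or above *d* Gy), Dmean, Dmax.

**Equieffective dose.** Voxel doses are converted to the equieffective dose
in the reference fractionation (n = 30 fractions) with the linear-quadratic
withdrawal: D′ solves D′(1 + D′/(n·α/β)) = D(1 + D/(n_s·α/β)), with
α/β = 2 Gy for brain.

**Equivalent uniform dose.** EUD is the generalized power mean of the voxel
doses,

> EUD = ( (1/N) Σᵢ Dᵢᵃ )^(1/a),   a = 9 for brain,

computed over the brain volume minus the serial OARs and gross tumour
(the "Brain_NTCP" structure, derived automatically).

**NTCP.** Normal-tissue complication probability follows the logistic
dose–response

> NTCP = 1 / (1 + (TD₅₀ / EUD)^k),   TD₅₀ = 55.5 Gy, k = 10.

Two plans are compared via the NTCP ratio NTCP_ex / NTCP_ref and the
increased risk IR = ln(1 − NTCP_ex) / ln(1 − NTCP_ref), the factor by which
the complication-free survival exponent grows.

**Contour similarity.** For reference mask A and submitted mask B:

> DSC = 2|A ∩ B| / (|A| + |B|),
> HD = max( h(A,B), h(B,A) ),  h(A,B) = max_{a∈∂A} min_{b∈∂B} ‖a − b‖,
> HD95 = max of the directed 95th-percentile surface distances.

Surface distances are exact (Euclidean distance transform of the boundary
voxels, mm-weighted per axis), not approximations.

**Scorecards.** YAML/JSON-declared constraint rules classify each metric as
*within protocol*, *acceptable variation*, or *deviation* (or *not
evaluable* when the structure is missing); the plan verdict is the worst
class observed.

## Worked example

Simulate a reference standard plan and a dose-escalated plan on the default
2 mm / 96³ head phantom, evaluate the radionecrosis risk, then perturb the
escalated plan into a mock centre submission and score it:

```r
library(planqa)

ref <- simulate_reference_bundle(plan = "standard", seed = 11)
esc <- simulate_reference_bundle(plan = "experimental", seed = 12)

risk <- evaluate_radionecrosis_risk(ref, esc)
risk
#> <risk_report> center 'reference'
#>   EUD  ref 49.2 Gy / ex 52.8 Gy
#>   NTCP ref 0.23 / ex 0.38  (ratio 1.65, IR 1.82)
glance(risk)
#> # A tibble: 1 × 7
#>   center    eud_ref eud_ex ntcp_ref ntcp_ex ntcp_ratio    ir
#>   <chr>       <dbl>  <dbl>    <dbl>   <dbl>      <dbl> <dbl>
#> 1 reference    49.2   52.8    0.230   0.379       1.65  1.82

sub <- generate_center_submission(
  esc, perturbation_profile(translation_sd = 2, boundary_sd = 1.5), seed = 5)

tidy(compare_structure_sets(esc$structures, sub$structures,
                            structures = c("GTVu", "PTV75", "Brainstem", "Pituitary")))
#> # A tibble: 4 × 7
#>   structure   dsc hd_mm hd95_mm volume_ref_cc volume_sub_cc evaluable
#>   <chr>     <dbl> <dbl>   <dbl>         <dbl>         <dbl> <lgl>
#> 1 GTVu      0.876  4.90    3.46        41.6          44.0   TRUE
#> 2 PTV75     0.899  4.90    3.46        75.8          80.6   TRUE
#> 3 Brainstem 0.662  8.25    6           10.8          11.0   TRUE
#> 4 Pituitary 0.290  4.90    4.47         0.288         0.208 TRUE

rules <- load_constraints(
  system.file("extdata", "constraints_example.yaml", package = "planqa"))
glance(evaluate_plan(sub, rules))
#> # A tibble: 1 × 8
#>   center plan  overall n_rules n_within n_acceptable n_deviation n_not_evaluable
#>   <chr>  <chr> <chr>     <int>    <int>        <int>       <int>           <int>
#> 1 cente… expe… deviat…       8        4            0           4               0
```

Note the similarity numbers: small structures (pituitary, ~0.3 cc) show low
DSC under the same millimetric perturbation that leaves large targets near
0.9 — exactly the size sensitivity Dice is known for, and a reason the
scorecard combines volumetric, dosimetric and distance-based checks.

A command-line interface with `simulate`, `dvh`, `compare`, `risk`, `score`
and `report` subcommands is installed at
`system.file("cli", "planqa", package = "planqa")` and runs under plain
`Rscript`.

## License

MIT (see `LICENSE`).
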