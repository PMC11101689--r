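# ILLUSTRATIVE constraint scorecard — NOT the bounds of any real trial
# protocol. Real bounds live in the trial manual and must replace this file.
# Metric specs: D{p}%, D{v}cc, Dmean, Dmax, V{d}Gy. Bounds are inclusive.
- structure: Brainstem
  metric: D0.03cc
  comparator: "<="
  per_protocol: 54
  acceptable: 59
  scope: both
- structure: OpticChiasm
  metric: D0.03cc
  comparator: "<="
  per_protocol: 54
  acceptable: 56
  scope: both
- structure: OpticNrv_L
  metric: D0.03cc
  comparator: "<="
  per_protocol: 54
  acceptable: 56
  scope: both
- structure: OpticNrv_R
  metric: D0.03cc
  comparator: "<="
  per_protocol: 54
  acceptable: 56
  scope: both
- structure: Pituitary
  metric: Dmean
  comparator: "<="
  per_protocol: 45
  scope: both
# Target coverage: D98 of each PTV at >= 95% of its prescription
- structure: PTV60
  metric: D98%
  comparator: ">="
  per_protocol: 0.95
  acceptable: 0.90
  relative_to_rx: true
  scope: standard
- structure: PTV60ex
  metric: D98%
  comparator: ">="
  per_protocol: 0.95
  acceptable: 0.90
  relative_to_rx: true
  scope: experimental
- structure: PTV75
  metric: D98%
  comparator: ">="
  per_protocol: 0.95
  acceptable: 0.90
  relative_to_rx: true
  scope: experimental
# Plausibility check on the unified GTV volume (cc): flags gross
# over-contouring such as edema inclusion
- structure: GTVu
  metric: V0Gy
  comparator: "<="
  per_protocol: 80
  acceptable: 100
  scope: experimental
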