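# Interpretation rule sets: published thresholds for CAD detection.
# Cutoffs are stress (hyperaemic) MBF in mL/min/g and MFR (unitless).
# `adjacency_requirement` is the number of mutually adjacent abnormal
# segments required to call the study abnormal (water convention).
# `sss_cutoff` is the summed-stress-score threshold for abnormality.
water-pacific:
  tracer: water
  stress_mbf_cutoff: 2.30
  mfr_cutoff: 2.5
  adjacency_requirement: 2
  sss_cutoff: ~
water-danad:
  tracer: water
  stress_mbf_cutoff: 1.86
  mfr_cutoff: 2.3
  adjacency_requirement: 2
  sss_cutoff: ~
ammonia-hajjiri:
  tracer: ammonia
  stress_mbf_cutoff: 1.85
  mfr_cutoff: 2.0
  adjacency_requirement: 1
  sss_cutoff: 4
rubidium-anagnostopoulos:
  tracer: rubidium
  stress_mbf_cutoff: 1.7
  mfr_cutoff: 2.0
  adjacency_requirement: 1
  sss_cutoff: 4
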