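{
  "_comment": "Default flow-dependent first-pass extraction models, K1 = MBF * E(MBF) with E(MBF) = 1 - a*exp(-b/MBF). Coefficients are taken from the cited primary literature (Lortie et al. 2007 for rubidium-82; the classic nitrogen-13 ammonia microsphere validation studies for ammonia), not measured here. They are configuration: edit or supply your own file via extraction_model().",
  "rubidium": { "form": "renkin_crone", "a": 0.77, "b": 0.63,
                "valid_range": [0.05, 8.0] },
  "ammonia":  { "form": "renkin_crone", "a": 0.607, "b": 1.25,
                "valid_range": [0.05, 8.0] },
  "water":    { "form": "identity" },
  "flurpiridaz": { "form": "identity" }
}
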