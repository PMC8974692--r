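# Trait-to-group mapping for PheWAS screening. Groups are curated, not
# inferred: traits not listed here are reported as "ungrouped". This bundled
# map is illustrative and covers the trait names emitted by the synthetic
# generator plus common UK-Biobank-style trait labels.
asthma:
  - asthma
  - self-reported asthma
blood/immune cell:
  - eosinophil count
  - eosinophil percentage
  - lymphocyte count
  - neutrophil count
  - monocyte count
  - platelet count
allergy:
  - hayfever/allergic rhinitis
  - atopic dermatitis
  - eczema/dermatitis
other respiratory:
  - copd
  - fev1
  - nasal polyps
inflammatory:
  - inflammatory bowel disease
  - ulcerative colitis
  - crohns disease
  - psoriasis
auto-immune:
  - insulin-dependent diabetes
  - rheumatoid arthritis
  - multiple sclerosis
  - hyperthyroidism
  - sarcoidosis
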