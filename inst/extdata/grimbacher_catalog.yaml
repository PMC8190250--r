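# Grimbacher-style clinical severity catalog: 15 CVID complications, each
# graded 0-3 (0 = absent, up to 3 = confirmed / severe / needing surgery);
# the grade value is its own point weight.
name: grimbacher
cluster_cutoff: 5
grades:
  "0": 0
  "1": 1
  "2": 2
  "3": 3
items:
  - autoimmunity
  - lymphoproliferation
  - enteropathy
  - malignancy
  - bronchiectasis
  - chronic_lung_disease
  - lung_surgery
  - splenectomy
  - splenomegaly
  - chronic_sinusitis
  - meningitis
  - encephalitis
  - pneumonia
  - severe_infection
  - granulomatous_disease
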