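# Ameratunga-style clinical severity catalog for CVID complications.
# Each complication is graded mild / moderate / severe, weighted 1 / 5 / 10.
# Default item set transcribed from the clinical-information summary of the
# CVID cohorts this scheme is applied to; edit freely for local use.
name: ameratunga
cluster_cutoff: 14
grades:
  mild: 1
  moderate: 5
  severe: 10
items:
  - recurrent_infections
  - pneumonia
  - chronic_lung_disease
  - bronchiectasis
  - glild
  - autoimmune_disease
  - granulomatous_disease
  - splenomegaly
  - enteropathy
  - malignancy
  - chronic_sinusitis
  - meningitis_encephalitis
  - surgical_intervention
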