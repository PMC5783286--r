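# Model configuration: four-state disability process with resolution.
# States are R (latent absorbing resolved), D0 (temporary non-disability),
# then n_severity increasing disability states D1..Dm.
n_severity: 2
resolution: true
lambda:
  "D0->R": 0.4
  "D0->D1": 0.4
  "D1->D0": 0.6
  "D1->D2": 0.6
  "D2->D1": 0.4
covariates:
  "D0->D1": {z: 1.0}
  "D1->D0": {z: 1.0}
  "D1->D2": {z: 1.0}
  "D2->D1": {z: 1.0}
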