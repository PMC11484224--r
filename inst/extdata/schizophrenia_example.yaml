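# Schizophrenia-trial planning scenario (Mehta & Pocock recruitment example):
# NSA-16 endpoint, assumed effect 1.6, SD 7.5, 345 patients per arm, interim
# after 200 observed outcomes with 208 patients in the pipeline.
alpha: 0.025
beta: 0.2
sigma: 7.5
n_max_per_arm: 345
info_interim: 0.29
info_pipeline: 0.3
spending_family: pocock_like
design_kind: DR_GSD
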