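# Demo pipeline configuration: simulate a default 41-subject cohort,
# phenotype the post-binge epoch, and run the sample-size stability
# analysis at the standard settings.
seed: 7
epoch: phenotyping
min_n: 15
cohort:
  n_subjects: 41
  event_epochs: []
stability:
  k_min: 2
  iterations: 100
  tolerance: 0.05
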