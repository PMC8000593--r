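# Desk-scale demonstration configuration: a small synthetic pre-train
# cohort drives the negative-mining workflow and a small target cohort is
# evaluated with two shuffled stratified splits.
seed: 1
out_dir: scintihot-demo
pretrain:
  n_positive: 10
  n_negative: 10
target:
  n_positive: 8
  n_negative: 8
normalize:
  t1: 7
  t2: 14
chest_band: [0.10, 0.45]
augment:
  low: 25
  high: 48
  n_levels: 2
  include_flips: true
mining:
  harvest_confidence: 0.1
cv:
  n_shuffles: 2
  k: 4
  decision_conf: 0.5
  iou: 0.3
  confidence_floor: 0.1
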