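# demo: end-to-end simulated run at desk scale
seed: 42
simulate: true
manipulation_night: 9
sim:
  n_bats: 8
  n_nights: 16
  n_trees: 250
  n_focal: 2
  extent: 8000
  n_manipulated: 3
  response_prob: 0.3
null_test:
  windows: [1, 2, 3, 4, 5, 6]
  min_cohort: 5
  n_iterations: 215
encounters:
  lags: [1, 2, 3]
out_dir: demo_out
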