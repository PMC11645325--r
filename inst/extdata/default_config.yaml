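# Default tuning configuration: the eight gradient-boosting
# hyperparameter axes with their experimental ranges, and the annealer
# settings (floor temperature 2, reheat multiplier 2, tabu capacity 20,
# 300 levels x 8 moves; cooling/initial-temperature/stall settings are
# package defaults, see the methods vignette).
search_space:
- name: n_estimators
  kind: integer
  lower: 1
  upper: 50
- name: max_depth
  kind: integer
  lower: 1
  upper: 50
- name: max_delta_step
  kind: integer
  lower: 1
  upper: 50
- name: num_parallel_tree
  kind: integer
  lower: 1
  upper: 50
- name: learning_rate
  kind: float
  lower: 0
  upper: 1
  lower_open: true
- name: reg_alpha
  kind: float
  lower: 0
  upper: 1
  lower_open: true
- name: reg_lambda
  kind: float
  lower: 0
  upper: 1
  lower_open: true
- name: gamma
  kind: float
  lower: 0
  upper: 50
  lower_open: true
atsa:
  t_min: 2
  t_init: 100
  beta: 2
  alpha: 0.95
  tabu_length: 20
  n_iterations: 300
  n_moves: 8
  stall_reheat: 10
  step_scale: 0.1
  seed: 1
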