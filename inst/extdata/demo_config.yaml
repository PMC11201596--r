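label: demo
seed: 1
simulate: yes
n_subjects: 200
n_nodes: 60
frames_per_block: 38
n_blocks_per_condition: 4
factor_loading: 0.677
effect_size: 0.2
base_connectivity: 0.2
coupling: 0.26
n_pos_edges: 10
n_neg_edges: 10
n_regions: 119
planted_receptors:
  5-HT1a_1: 0.9
  GABAa_2: 0.9
condition: punishment
scheme: loocv
k: 5
repeats: 10
p_threshold: 0.01
network: combined
n_perm: 99
consensus: 0.9
alpha: 0.05
flip:
- days_since_last_drink
- age_first_drink
- longest_abstinence
anchor: total_drinks_week
inputs: []
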