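# Default run configuration for the limited-offer task: an 8-trial game with
# a 30p standing offer and an 80p high offer, played by the control phenotype.
task:
  horizon: 8
  low_offer: 30
  high_offer: 80
  base_withdrawal_hazard: 0.12
  base_offer_prob: 0.05
  offer_decay: 0.7
agent:
  preset: control
simulation:
  n_games: 256
  seed: 1
fit:
  true_params:
    - prior_precision: 4
    - prior_precision: 8
    - prior_precision: 16
  n_reps: 2
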