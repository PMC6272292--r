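# RF-vs-MLR ordering on nonlinear labels: one training size, 10 RF seeds.
name: rf-vs-mlr
kind: volume
generator:
  n_protein_atoms: 80
  n_ligand_atoms: 22
labels:
  mechanism: nonlinear
  noise_sd: 0.5
  nonlinear_strength: 1.0
n_test: 400
training_sizes: [2000]
models: [vina, mlr_vina, rf_vina]
n_seeds: 10
n_trees: 500
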