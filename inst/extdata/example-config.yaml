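# Decade concentration sweep at the study conditions.  All keys are
# optional except concentration(s); defaults are documented in ?run_config
# and echoed by effective_config().
concentrations: [5.0e-9, 5.0e-8, 5.0e-7, 5.0e-6, 5.0e-5, 5.0e-4, 5.0e-3, 5.0e-2]
total_peptides: 10000
seed: 1
replicates: 10
max_time: 1.0e4
solvent:
  temperature: 300      # K
  viscosity: 8.9e-4     # Pa s
polymorphs: [AP, P]
# Interface energies (kcal/mol per buried peptide) and lattices default to
# the published IFQINS parameterisation; override like so:
# ap_spec:
#   lattice: {a: 20.0, b: 19.1, c: 4.8, gamma: 83, peptides_per_cell: [1, 2, 1]}
#   energies: {dG_a: -9.2, dG_b: -6.2, dG_zip: -16.4, dG_c: -29.3}
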