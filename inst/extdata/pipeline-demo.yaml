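# Demo pipeline configuration: simulate a small structured collection and
# run the full curation + diversity analysis on it.
seed: 7
output_dir: corecurator-output
simulate:
  n_markers: 250
  n_per_subpop: [15, 20, 20, 15, 8]
  n_admixed: 40
  duplicate_sets: [2, 3]
  qtl:
    markers: [40, 120, 200]
    effect: 1
  heritability: 0.5
phipt:
  n_perm: 199
ld:
  n_unlinked_pairs: 5000
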