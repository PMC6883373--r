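{
  "seed": 7,
  "sim": {
    "n_populations": 2,
    "lines_per_population": [30, 30],
    "phenotyped_per_population": [20, 20],
    "n_chromosomes": 2,
    "markers_per_chromosome": 50,
    "n_qtl": 20,
    "blocks_per_rep": 4,
    "n_checks": 2
  },
  "chain": { "iters": 2000, "burnin": 500, "thin": 2 },
  "cv": { "k": 4, "n_repeats": 2, "iters": 400, "burnin": 100 },
  "selection_fraction": 0.15,
  "stage2": { "n_testers": 2 }
}
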