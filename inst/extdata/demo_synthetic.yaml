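# Demo: simulate an F2 recombinant-congenic cross with one planted QTL and
# one epistatic pair, then scan it.
seed: 1
output_dir: qtlcoloc-synthetic
simulate:
  map: marker_map_synthetic.csv
  regions: segregating_regions_synthetic.csv
  n: 226
  qtls:
    - marker: D5Mit68
      additive: 0.4
      trait: number
  interactions:
    - marker_a: D8Mit17
      marker_b: D18Mit17
      effect: 0.6
      trait: number
scan:
  trait: number
  alpha: 0.05
  transform: log1p
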