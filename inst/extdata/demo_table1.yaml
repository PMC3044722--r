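# Demo: reproduce the published co-localization analyses from the packaged
# region/locus tables.  Positions flagged synthetic in the fixtures are
# curated stand-ins consistent with the printed distance classes.
seed: 1
output_dir: qtlcoloc-table1
coloc:
  region_table: table1_regions.csv
  count_a: 14          # detected colon susceptibility loci
  count_b: 30          # detected lung susceptibility loci
  tested_length_cM: 630   # 45% of a 1400 cM map
  df: 3
  nsim: 10000
proximity:
  query: fig6_loci_synthetic.csv
  species: human
  trait: colon
  anchors: sluc_anchors_synthetic.csv
  tested: ocb_tested_synthetic.csv
  w: 7          # upper bound of the "relatively close" distance class
  nperm: 5000
clusters:
  loci: [fig6_loci_synthetic.csv, sluc_anchors_synthetic.csv]
  threshold: 10
  flag_within: 2.5
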