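spliceai_min: 0.2
revel_pathogenic:
  supporting: 0.644
  moderate: 0.773
  strong: 0.932
revel_benign:
  supporting: 0.29
  moderate: 0.183
  strong: 0.016
  very_strong: 0.003
pm2_af_max: 0.002
pm2_strength: moderate
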