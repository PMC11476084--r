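cohorts:
- name: global
  n_individuals: 125748
  source: gnomad-exomes
  members:
  - afr
  - amr
  - asj
  - east_asian
  - fin
  - nfe
  - sas
  - oth
- name: east_asian
  n_individuals: 9197
  source: gnomad-exomes
  members:
  - kor
  - jpn
  - oea
- name: afr
  n_individuals: 8128
  source: gnomad-exomes
  table: gnomad
  population: afr
- name: amr
  n_individuals: 17296
  source: gnomad-exomes
  table: gnomad
  population: amr
- name: asj
  n_individuals: 5040
  source: gnomad-exomes
  table: gnomad
  population: asj
- name: fin
  n_individuals: 10824
  source: gnomad-exomes
  table: gnomad
  population: fin
- name: nfe
  n_individuals: 56885
  source: gnomad-exomes
  table: gnomad
  population: nfe
- name: sas
  n_individuals: 15308
  source: gnomad-exomes
  table: gnomad
  population: sas
- name: oth
  n_individuals: 3070
  source: gnomad-exomes
  table: gnomad
  population: oth
- name: kor
  n_individuals: 1909
  source: gnomad-exomes
  table: gnomad
  population: kor
- name: jpn
  n_individuals: 76
  source: gnomad-exomes
  table: gnomad
  population: jpn
- name: oea
  n_individuals: 7212
  source: gnomad-exomes
  table: gnomad
  population: oea
- name: all_korean
  n_individuals: 8936
  source: pooled
  members:
  - kor
  - kova
  - krgdb
- name: kova
  n_individuals: 5305
  source: kova
  table: kova
  population: kova
- name: krgdb
  n_individuals: 1722
  source: krgdb
  table: krgdb
  population: krgdb
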