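# Example run configuration. The scenario list below spells out the eight
# standard combinations explicitly; deleting the whole `scenarios` key (or
# using an empty file) gives the identical default set.
substeps: 10
scenarios:
  - {id: 1, variant: 1, R: 3.2, trend: 0.00}
  - {id: 2, variant: 2, R: 3.2, trend: 0.00}
  - {id: 3, variant: 1, R: 1.17, trend: 0.00}
  - {id: 4, variant: 2, R: 1.17, trend: 0.00}
  - {id: 5, variant: 1, R: 3.2, trend: 0.02}
  - {id: 6, variant: 2, R: 3.2, trend: 0.02}
  - {id: 7, variant: 1, R: 1.17, trend: 0.02}
  - {id: 8, variant: 2, R: 1.17, trend: 0.02}
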