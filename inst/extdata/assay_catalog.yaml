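# Default assay catalog.
# Hit rates are lower-bound estimates taken from diagnostic rates for severe
# intellectual disability under each assay; replace with disease-specific
# values where known. Prices are relative (chip-unit = 1).
assays:
  - name: chip-CNV
    hit_rate: 0.12
    price: 1
  - name: WES
    hit_rate: 0.27
    price: 4
  - name: WGS
    hit_rate: 0.62
    price: 16
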