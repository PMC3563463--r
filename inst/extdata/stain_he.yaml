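# H&E stain matrix: rows hematoxylin, eosin, residual (row-major);
# columns red, green, blue OD components. Rows are renormalized on load.
matrix:
  - 0.65
  - 0.70
  - 0.29
  - 0.07
  - 0.99
  - 0.11
  - -0.2103
  - -0.0514
  - 0.5963
I0: 255
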