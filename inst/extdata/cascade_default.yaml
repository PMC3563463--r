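# Default cascade: cancer vs non-cancer, then grade and confounder splits.
name: cancer_vs_noncancer
left: [G3, G4, G5]
right: [BE, BS, AT, PIN]
left_child:
  name: g34_vs_g5
  left: [G3, G4]
  right: [G5]
  left_child:
    name: g3_vs_g4
    left: [G3]
    right: [G4]
right_child:
  name: confounder_vs_normal
  left: [AT, PIN]
  right: [BE, BS]
  left_child:
    name: at_vs_pin
    left: [AT]
    right: [PIN]
  right_child:
    name: be_vs_bs
    left: [BE]
    right: [BS]
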