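columns:
  girth_cm: girth_cm
  height_cm: height_cm
depth_unit: cm
site_aliases:
  axial: axilla
  mid-seal: mid
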