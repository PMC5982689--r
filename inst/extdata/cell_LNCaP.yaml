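# LNCaP cell gripped by the default device.  Reference modulus from
# published AFM measurements of prostate cell lines.
extends: paper_default
cell:
  E_c: {value: 287, unit: Pa}
  v: 0.5
  R: {value: 10, unit: um}
  label: LNCaP
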