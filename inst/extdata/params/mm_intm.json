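{
  "name": "mm_intm",
  "version": "1.0.0",
  "g": 62.00,
  "E": -3.64,
  "tauO_I": [1.70, 1.49, 0.035],
  "tauO_V": [0.29, 48.56, 738.24],
  "tauR_I": [0.17, 0.0081, -2.80, 14.69, 1.05, 0.42],
  "tauR_V": [24.77, 80.92, 164.75],
  "Oinf": [3.76, 0.40],
  "Rinf": [0.74, 0.52, 1.00],
  "combine_O": "product",
  "combine_R": "product",
  "mode": "absolute"
}
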