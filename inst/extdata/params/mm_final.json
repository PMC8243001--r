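{
  "name": "mm_final",
  "version": "1.0.0",
  "g": 62.22,
  "E": -3.62,
  "tauO_I": [3.70, 3.35, 0.037],
  "tauO_V": [0.20, 49.99, 718.60],
  "tauR_I": [0.18, 0.0082, -3.00, 15.57, 0.998, 0.429],
  "tauR_V": [24.42, 80.87, 172.82],
  "Oinf": [3.67, 0.39],
  "Rinf": [0.40, 0.54, 0.9987],
  "combine_O": "product",
  "combine_R": "product",
  "mode": "absolute"
}
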