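{
  "name": "pp_final",
  "version": "1.0.0",
  "g": 1,
  "E": 0,
  "tauO_I": [1.93, 0.88, 0.030],
  "tauO_V": [0.63, -88.67, 8.37],
  "tauR_I": [6.73, 0.50, 1.98, 0.11, -1.28, 0.88],
  "tauR_V": [1.66, -64.54, 28.55],
  "Oinf": [3.44, 0.68],
  "Rinf": [2.25, 0.065, 0.75],
  "Grect": [9.10, 1.27, 41.47],
  "combine_O": "product",
  "combine_R": "product",
  "mode": "density"
}
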