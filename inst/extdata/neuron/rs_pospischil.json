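{
  "name": "rs_cortical",
  "version": "1.0.0",
  "description": "Regular-spiking cortical pyramidal single-compartment model: leak, transient Na, delayed-rectifier K and slow non-inactivating M-type K with threshold-shifted Traub kinetics (Pospischil et al. 2008 RS parameter set).",
  "C_uF_cm2": 1.0,
  "g_leak_mS_cm2": 0.0205,
  "E_leak_mV": -70.3,
  "g_Na_mS_cm2": 56.0,
  "E_Na_mV": 50.0,
  "g_Kd_mS_cm2": 6.0,
  "g_M_mS_cm2": 0.075,
  "E_K_mV": -90.0,
  "V_T_mV": -56.2,
  "tau_max_ms": 608.0
}
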