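{
  "delta_eps": -2.42,
  "kd_on": 2.18,
  "kd_off": 0.002,
  "J": -3.81,
  "mu_w0": -0.67,
  "mu_a2_0": -1.68,
  "rho": 3.13,
  "x_max": 4,
  "scheme": "bridged",
  "mod_label": "QEQE"
}
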