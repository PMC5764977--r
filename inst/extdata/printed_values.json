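{
  "version": "1.0",
  "fig3e": [
    {"lipid": "SM",   "frequency": 2.7e9, "mu": 8.99e-4, "sigma": 1.56e-4},
    {"lipid": "SM",   "frequency": 7.9e9, "mu": 9.35e-4, "sigma": 0.57e-4},
    {"lipid": "POPC", "frequency": 2.7e9, "mu": 4.09e-4, "sigma": 0.87e-4},
    {"lipid": "POPC", "frequency": 7.9e9, "mu": 3.11e-4, "sigma": 0.97e-4}
  ],
  "two_domain": [
    {"guv": 1, "frequency": 2.7e9, "section_I": 10.64e-4, "section_II": 4.55e-4,
     "label_I": "SM", "label_II": "POPC"},
    {"guv": 2, "frequency": 2.7e9, "section_I": 7.32e-4, "section_II": 2.92e-4,
     "label_I": "SM", "label_II": "POPC"},
    {"guv": 3, "frequency": 2.7e9, "section_I": 9.29e-4, "section_II": 4.74e-4,
     "label_I": "SM", "label_II": "POPC"},
    {"guv": 4, "frequency": 7.9e9, "section_I": 7.91e-4, "section_II": 2.71e-4,
     "label_I": "SM", "label_II": "POPC"}
  ],
  "permittivity": [
    {"lipid": "POPC", "frequency": 2.7e9, "elevation_nm": 0,
     "eps_real": 73.64, "eps_imag": 6.13},
    {"lipid": "SM",   "frequency": 2.7e9, "elevation_nm": 100,
     "eps_real": 73.17, "eps_imag": 1.34},
    {"lipid": "SM",   "frequency": 7.9e9, "elevation_nm": 100,
     "eps_real": 62.75, "eps_imag": 0.65},
    {"lipid": "POPC", "frequency": 2.7e9, "elevation_nm": 100,
     "eps_real": 73.34, "eps_imag": 5.66},
    {"lipid": "POPC", "frequency": 7.9e9, "elevation_nm": 100,
     "eps_real": 63.61, "eps_imag": 15.41}
  ],
  "theta0": [
    {"frequency": 2.7e9, "theta0_deg": 103.9},
    {"frequency": 7.9e9, "theta0_deg": 339.88}
  ],
  "constants": {
    "scan_duration_range_s": [0.6, 0.9],
    "flow_rate_ul_min": 2,
    "ifbw_hz": 1000,
    "membrane_thickness_nm": {"SM": 5.0, "POPC": 4.0},
    "two_domain_composition": {"SM": 0.65, "POPC": 0.10, "cholesterol": 0.25}
  }
}
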