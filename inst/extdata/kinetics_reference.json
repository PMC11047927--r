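{
  "comment": "Published BLI kinetic constants and dose-response EC50s used as simulation targets. In the source table the ka values for 8H9 and A6 are printed with a 1e-4 exponent, inconsistent with the printed KD = kd/ka; the 1e4 scale reproduces the printed KD and is used here (flagged by ka_exponent_typo). kd, KD and half-life are authoritative.",
  "antibodies": {
    "8H9": {"ka_1_Ms": 2.36e4, "kd_1_s": 2.40e-4, "KD_nM": 10.16,
            "KD_error_nM": 0.29, "half_life_s": 2885,
            "ka_exponent_typo": true},
    "A6":  {"ka_1_Ms": 1.00e4, "kd_1_s": 3.09e-4, "KD_nM": 30.90,
            "KD_error_nM": 0.63, "half_life_s": 2243,
            "ka_exponent_typo": true},
    "a13": {"ka_1_Ms": 3.87e4, "kd_1_s": 2.89e-3, "KD_nM": 74.70,
            "KD_error_nM": 0.96, "half_life_s": 240,
            "ka_exponent_typo": false}
  },
  "bli_protocol": {
    "t_assoc_s": 300,
    "t_dissoc_s": 600,
    "concentrations_nM": [900, 300, 100, 33],
    "rmax_nm": 1.5,
    "noise_sd_nm": 0.005
  },
  "dose_response": {
    "elisa_A6_hFc":  {"ec50_nM": 0.33, "scheme": "3-fold from 300 nM, 8 points, duplicates", "top_dose_M": 3e-7, "dilution": 3, "points": 8, "replicates": 2},
    "elisa_8H9":     {"ec50_nM": 0.16, "scheme": "3-fold from 300 nM, 8 points, duplicates", "top_dose_M": 3e-7, "dilution": 3, "points": 8, "replicates": 2},
    "elisa_a13_hFc": {"ec50_nM": 1.75, "scheme": "3-fold from 300 nM, 8 points, duplicates", "top_dose_M": 3e-7, "dilution": 3, "points": 8, "replicates": 2},
    "adcc_A6_hFc_SDIE": {"ec50_nM": 0.67, "scheme": "5-fold from 10 uM, 8 points, triplicates", "top_dose_M": 1e-5, "dilution": 5, "points": 8, "replicates": 3},
    "adcc_A6_hFc_WT":   {"ec50_nM": 81.5, "scheme": "5-fold from 10 uM, 8 points, triplicates", "top_dose_M": 1e-5, "dilution": 5, "points": 8, "replicates": 3}
  }
}
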