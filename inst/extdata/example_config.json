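{
  "seed": 1,
  "carrier": {
    "name": "Cytodex 3 (synthetic fixture)",
    "area_per_gram": 2700,
    "max_area_density": 450000
  },
  "model": {
    "params": {
      "mu_max": 0.04,
      "K_S_LS": 0.08,
      "mu_d_min": 0.004,
      "mu_d_max": 0.015,
      "K_d_LS": 0.08,
      "k_att_max": 0.25,
      "t_att": 20,
      "K_Lys": 0.01,
      "Y_X_Glc": 400000,
      "k_Glc": 0.5,
      "Y_X_Gln": 1000000,
      "k_Gln": 0.2,
      "q_LS_max": 1.4e-08,
      "k_LS": 0.05,
      "Y_Lac_Glc": 1.6,
      "Y_Amm_Gln": 0.7
    },
    "death_mode": "printed"
  },
  "synthesis": {
    "noise": 0.15,
    "sample_times": [0, 24, 48, 72, 96, 120, 168, 216, 264, 312]
  },
  "factor_space": {
    "names": ["c_Glc", "c_Gln", "c_MC"],
    "lower": [5, 2, 1],
    "upper": [60, 12, 20],
    "units": ["mmol/L", "mmol/L", "g/L"]
  },
  "designs": [
    {
      "type": "ccd",
      "center_replicates": 6
    },
    {
      "type": "bbd",
      "center_replicates": 12
    },
    {
      "type": "lhs",
      "n": 16
    },
    {
      "type": "d_optimal",
      "n": 16
    },
    {
      "type": "i_optimal",
      "n": 16
    },
    {
      "type": "lhsd_d_optimal",
      "n": 16,
      "n_lhs_candidates": 64
    }
  ],
  "calibration": {
    "n_starts": 3,
    "init_factor": 1.5,
    "mc_n": 100,
    "mc_noise": 0.15,
    "mc_mode": "refit"
  },
  "evaluation": {
    "n_sim": 100,
    "metric": "per_cm2",
    "top_k": 2,
    "t_end": 336,
    "dt": 4
  }
}
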