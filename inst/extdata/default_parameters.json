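{
  "tumor_type": "primary",
  "ecm_type": "cECM",
  "polarization_enabled": true,
  "grid_nodes_per_side": 61,
  "rng_seed": 1,
  "t_end": 13,
  "dt": 0.1,
  "output_interval": 0.5,
  "seed_radius_nodes": 3,
  "tumor": {
    "lambda_M": 0.8,
    "lambda_A": 0.05,
    "G_N": 0.1,
    "Q_OL_bar": 0.45,
    "Q_OL_min": 0.25,
    "necrotic_threshold": 0.22,
    "lambda_OL": 1,
    "lambda_OT": 1,
    "lambda_F": 1.5
  },
  "mechanics": {
    "mu": 1,
    "chi_E": 0.05
  },
  "oxygen": {
    "D_sigma": 0.04,
    "lambda_tissue": 1,
    "lambda_tumor": 10,
    "q_sigma": 3,
    "lambda_N": 0.5
  },
  "ecm": {
    "lambda_production": 0.3,
    "lambda_sprout_production": 0.15,
    "lambda_degradation": 1.5,
    "k_p": 1,
    "k_d": 1,
    "E_far_cECM": 0.4,
    "E_far_tECM": 0.6,
    "E_far": 0.4
  },
  "mde": {
    "D_M": 0.0008,
    "lambda_production": 1,
    "lambda_sprout_production": 0.5,
    "lambda_degradation": 0.5,
    "lambda_decay": 1,
    "k_d": 1
  },
  "macrophage": {
    "extravasation_rate": 1,
    "motility": 20,
    "w_chem": 3,
    "w_oxy": 4,
    "w_press": 2,
    "m1_center_bias_weight": 1,
    "tnf_threshold": 0.13,
    "tgf_threshold": 0.12,
    "polarization_prob": 1.1,
    "lambda_NO": 0.006,
    "m1_neighborhood": 3,
    "microenv_margin": 8
  },
  "vessel": {
    "line_spacing_primary": 15,
    "line_spacing_metastatic": 13,
    "sprout_rate": 1,
    "tip_step": 5,
    "taf_sprout_threshold": 0.1,
    "anastomosis_radius": 1,
    "lambda_pre_sigma": 28,
    "lambda_neo_sigma": 28,
    "hematocrit_h": 0.45,
    "p_eff": 5
  },
  "cytokines": {
    "TNF": {
      "name": "TNF",
      "D_C": 0.02,
      "lambda_production": 2.5,
      "lambda_circulation": 2,
      "lambda_decay": 2,
      "production_region": "hypoxic_tumor"
    },
    "TGFB1": {
      "name": "TGFB1",
      "D_C": 0.15,
      "lambda_production": 1.8,
      "lambda_circulation": 1,
      "lambda_decay": 0.8,
      "production_region": "viable_tumor"
    },
    "TAF": {
      "name": "TAF",
      "D_C": 0.06,
      "lambda_production": 2,
      "lambda_circulation": 5,
      "lambda_decay": 1,
      "production_region": "hypoxic_tumor"
    },
    "F": {
      "name": "F",
      "D_C": 0.05,
      "lambda_production": 15,
      "lambda_circulation": 1,
      "lambda_decay": 2,
      "production_region": "M2_agents"
    }
  }
}
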