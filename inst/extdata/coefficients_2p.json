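{
  "chicken_structural_protein": {
    "lambda1": 0.813, "lambda2": -0.077, "lambda3": -0.874,
    "se1": 0.049, "se2": 0.024, "se3": 0.223,
    "n": 46, "r2": 0.882, "adj_r2": 0.877, "f_stat": 161.7, "rmse": 0.323,
    "intercept_dropped": false, "source": "current study"
  },
  "fish_structural_protein": {
    "lambda1": 0.886, "lambda2": -0.097, "lambda3": -1.243,
    "se1": 0.055, "se2": 0.027, "se3": 0.246,
    "n": 45, "r2": 0.870, "adj_r2": 0.864, "f_stat": 140.8, "rmse": 0.353,
    "intercept_dropped": false, "source": "current study"
  },
  "combined_structural_protein": {
    "lambda1": 0.851, "lambda2": -0.092, "lambda3": -1.080,
    "se1": 0.049, "se2": 0.025, "se3": 0.220,
    "n": 51, "r2": 0.878, "adj_r2": 0.873, "f_stat": 173.3, "rmse": 0.334,
    "intercept_dropped": false, "source": "current study"
  },
  "bsa": {
    "lambda1": 0.788, "lambda2": -0.053, "lambda3": 0.000,
    "se1": 0.046, "se2": 0.018, "se3": null,
    "n": 83, "r2": 0.760, "adj_r2": 0.759, "f_stat": 130.5, "rmse": 0.422,
    "intercept_dropped": true, "source": "current study"
  },
  "phospholipid": {
    "lambda1": 1.070, "lambda2": -0.056, "lambda3": -0.247,
    "se1": 0.021, "se2": 0.013, "se3": 0.095,
    "n": null, "r2": 0.953, "adj_r2": 0.952, "f_stat": 1293, "rmse": 0.414,
    "intercept_dropped": false, "source": "Khawar et al. (lipid 2p-LFERs)"
  },
  "storage_lipid": {
    "lambda1": 1.102, "lambda2": 0.069, "lambda3": -0.236,
    "se1": 0.016, "se2": 0.010, "se3": 0.043,
    "n": null, "r2": 0.971, "adj_r2": 0.970, "f_stat": 5046, "rmse": 0.375,
    "intercept_dropped": false, "source": "Khawar et al. (lipid 2p-LFERs)"
  }
}
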