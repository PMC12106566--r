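{
  "L1-L2": {
    "intercept": 142.3,
    "coef_t2_per_ms": -0.3950,
    "coef_height_per_inch": -1.050,
    "coef_area_per_mm2": -0.04852,
    "coef_volume_per_mm3": 0.002585,
    "r2": 0.68,
    "rmse_years": 10.4
  },
  "L2-L3": {
    "intercept": 140.2,
    "coef_t2_per_ms": -0.3879,
    "coef_height_per_inch": -0.8855,
    "coef_area_per_mm2": -0.07195,
    "coef_volume_per_mm3": 0.002040,
    "r2": 0.70,
    "rmse_years": 10.1
  },
  "L3-L4": {
    "intercept": 163.4,
    "coef_t2_per_ms": -0.3645,
    "coef_height_per_inch": -1.263,
    "coef_area_per_mm2": -0.1058,
    "coef_volume_per_mm3": 0.002737,
    "r2": 0.77,
    "rmse_years": 8.8
  },
  "L4-L5": {
    "intercept": 156.3,
    "coef_t2_per_ms": -0.3319,
    "coef_height_per_inch": -1.297,
    "coef_area_per_mm2": -0.09644,
    "coef_volume_per_mm3": 0.002920,
    "r2": 0.62,
    "rmse_years": 11.3
  },
  "L5-S1": {
    "intercept": 165.8,
    "coef_t2_per_ms": -0.2701,
    "coef_height_per_inch": -1.498,
    "coef_area_per_mm2": -0.1399,
    "coef_volume_per_mm3": 0.004336,
    "r2": 0.43,
    "rmse_years": 13.8
  }
}
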