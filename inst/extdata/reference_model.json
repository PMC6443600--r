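{
  "feature_ids": [
    "cluster_shade_cooccurrence",
    "variance_first_order",
    "low_gray_level_run_emphasis",
    "gabor_response_variance_8",
    "gabor_response_variance_12",
    "gabor_response_variance_24",
    "gabor_response_entropy_26",
    "gabor_response_variance_28"
  ],
  "weights": [5.65412e-11, -2.726245e-04, -1.980131e+01, -3.909510e-03,
              -1.039332e-17, -1.021795e-05, 6.648282e-02, -5.733282e-11],
  "cutoff": -1.117,
  "reference_flag": true
}
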