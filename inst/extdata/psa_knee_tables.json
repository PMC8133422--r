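{
  "description": "Reference clinical dataset: knee trabecular microarchitecture (8 ROIs x 4 metrics; 7 controls vs 1 PsA patient before/after one year of anti-TNFa treatment) and FNa-PET SUV summaries for the same ROIs. Values are group summaries (mean, sd) and per-ROI SUVmean/SUVmax as published; sig_* flags transcribe the printed p<0.01 markers.",
  "n_controls": 7,
  "replicates_per_subject": 3,
  "suv_threshold": 2.5,
  "suv": {
    "ROI1":  {"before": {"mean": 2.7, "sd": 0.5, "max": 3.79}, "after": {"mean": 2.1, "sd": 0.6, "max": 3.77}},
    "ROI1a": {"before": {"mean": 2.6, "sd": 0.4, "max": 3.72}, "after": {"mean": 2.4, "sd": 0.4, "max": 3.18}},
    "ROI1b": {"before": {"mean": 2.9, "sd": 0.5, "max": 3.77}, "after": {"mean": 1.6, "sd": 0.5, "max": 3.02}},
    "ROI1c": {"before": {"mean": 2.7, "sd": 0.4, "max": 3.79}, "after": {"mean": 2.3, "sd": 0.6, "max": 3.69}},
    "ROI2":  {"before": {"mean": 1.9, "sd": 0.5, "max": 3.34}, "after": {"mean": 1.2, "sd": 0.6, "max": 3.32}},
    "ROI3":  {"before": {"mean": 1.9, "sd": 0.5, "max": 4.06}, "after": {"mean": 1.0, "sd": 0.3, "max": 2.41}},
    "ROI3a": {"before": {"mean": 2.8, "sd": 0.4, "max": 4.06}, "after": {"mean": 1.3, "sd": 0.4, "max": 2.41}},
    "ROI3b": {"before": {"mean": 2.0, "sd": 0.2, "max": 2.82}, "after": {"mean": 0.7, "sd": 0.1, "max": 1.12}}
  },
  "micro": {
    "ROI1": {
      "bvf":   {"control": [0.375, 0.015], "before": [0.297, 0.011], "after": [0.373, 0.016], "sig_before": true,  "sig_after": false},
      "tb_th": {"control": [0.258, 0.005], "before": [0.257, 0.004], "after": [0.276, 0.003], "sig_before": false, "sig_after": true},
      "tb_sp": {"control": [0.429, 0.065], "before": [0.643, 0.036], "after": [0.470, 0.013], "sig_before": true,  "sig_after": false},
      "tb_n":  {"control": [1.455, 0.076], "before": [1.132, 0.068], "after": [1.347, 0.008], "sig_before": true,  "sig_after": false}
    },
    "ROI1a": {
      "bvf":   {"control": [0.393, 0.008], "before": [0.339, 0.018], "after": [0.401, 0.010], "sig_before": true,  "sig_after": false},
      "tb_th": {"control": [0.255, 0.013], "before": [0.254, 0.022], "after": [0.266, 0.014], "sig_before": false, "sig_after": false},
      "tb_sp": {"control": [0.364, 0.032], "before": [0.477, 0.058], "after": [0.365, 0.008], "sig_before": false, "sig_after": false},
      "tb_n":  {"control": [1.550, 0.074], "before": [1.301, 0.136], "after": [1.493, 0.073], "sig_before": false, "sig_after": false}
    },
    "ROI1b": {
      "bvf":   {"control": [0.355, 0.035], "before": [0.222, 0.064], "after": [0.328, 0.027], "sig_before": true,  "sig_after": false},
      "tb_th": {"control": [0.261, 0.010], "before": [0.250, 0.015], "after": [0.285, 0.004], "sig_before": false, "sig_after": true},
      "tb_sp": {"control": [0.469, 0.117], "before": [0.651, 0.057], "after": [0.532, 0.064], "sig_before": true,  "sig_after": false},
      "tb_n":  {"control": [1.366, 0.114], "before": [0.994, 0.090], "after": [1.116, 0.083], "sig_before": true,  "sig_after": false}
    },
    "ROI1c": {
      "bvf":   {"control": [0.377, 0.015], "before": [0.295, 0.026], "after": [0.375, 0.016], "sig_before": true,  "sig_after": false},
      "tb_th": {"control": [0.207, 0.008], "before": [0.213, 0.005], "after": [0.225, 0.003], "sig_before": false, "sig_after": true},
      "tb_sp": {"control": [0.366, 0.042], "before": [0.632, 0.096], "after": [0.424, 0.005], "sig_before": true,  "sig_after": false},
      "tb_n":  {"control": [1.746, 0.250], "before": [1.409, 0.119], "after": [1.661, 0.024], "sig_before": true,  "sig_after": false}
    },
    "ROI2": {
      "bvf":   {"control": [0.354, 0.048], "before": [0.257, 0.015], "after": [0.312, 0.007], "sig_before": true,  "sig_after": false},
      "tb_th": {"control": [0.261, 0.005], "before": [0.260, 0.006], "after": [0.269, 0.006], "sig_before": false, "sig_after": false},
      "tb_sp": {"control": [0.516, 0.140], "before": [0.769, 0.025], "after": [0.656, 0.009], "sig_before": true,  "sig_after": false},
      "tb_n":  {"control": [1.342, 0.187], "before": [1.016, 0.020], "after": [1.173, 0.054], "sig_before": true,  "sig_after": false}
    },
    "ROI3": {
      "bvf":   {"control": [0.337, 0.019], "before": [0.219, 0.015], "after": [0.256, 0.012], "sig_before": true,  "sig_after": true},
      "tb_th": {"control": [0.266, 0.011], "before": [0.245, 0.004], "after": [0.257, 0.008], "sig_before": true,  "sig_after": false},
      "tb_sp": {"control": [0.562, 0.087], "before": [0.924, 0.029], "after": [0.866, 0.053], "sig_before": true,  "sig_after": true},
      "tb_n":  {"control": [1.261, 0.109], "before": [0.879, 0.051], "after": [0.985, 0.043], "sig_before": true,  "sig_after": true}
    },
    "ROI3a": {
      "bvf":   {"control": [0.381, 0.009], "before": [0.307, 0.016], "after": [0.335, 0.018], "sig_before": true,  "sig_after": false},
      "tb_th": {"control": [0.258, 0.008], "before": [0.260, 0.009], "after": [0.267, 0.012], "sig_before": false, "sig_after": false},
      "tb_sp": {"control": [0.426, 0.060], "before": [0.594, 0.012], "after": [0.570, 0.016], "sig_before": true,  "sig_after": true},
      "tb_n":  {"control": [1.468, 0.073], "before": [1.185, 0.047], "after": [1.241, 0.029], "sig_before": true,  "sig_after": true}
    },
    "ROI3b": {
      "bvf":   {"control": [0.376, 0.018], "before": [0.242, 0.024], "after": [0.285, 0.013], "sig_before": true,  "sig_after": true},
      "tb_th": {"control": [0.220, 0.015], "before": [0.192, 0.005], "after": [0.202, 0.011], "sig_before": true,  "sig_after": false},
      "tb_sp": {"control": [0.418, 0.061], "before": [0.636, 0.054], "after": [0.539, 0.033], "sig_before": true,  "sig_after": false},
      "tb_n":  {"control": [1.689, 0.148], "before": [1.255, 0.183], "after": [1.432, 0.094], "sig_before": true,  "sig_after": false}
    }
  }
}
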