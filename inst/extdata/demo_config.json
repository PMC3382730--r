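{
  "seed": 7,
  "fs_hz": 312.5,
  "sensors": "sensors.tsv",
  "parcellation": "parcellation.tsv",
  "head": {
    "center_m": [0, 0, 0],
    "radius_m": 0.09
  },
  "simulate": {
    "n_subjects": 1,
    "duration_s": 66,
    "carrier_band": [8, 13],
    "noise_fraction": 0.1,
    "amplitude_nam": 20,
    "sensor_noise_t": 5e-14,
    "couplings": [
      {
        "i": 1,
        "j": 2,
        "lag": 0.785398163397448,
        "strength": 0.8
      },
      {
        "i": 3,
        "j": 4,
        "lag": 1.0471975511966,
        "strength": 0.8
      }
    ]
  },
  "estimator": "pli",
  "epoch_length": 4096,
  "n_epochs": 5,
  "R": 100,
  "alpha": 0.05,
  "analysis_bands": "alpha"
}
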