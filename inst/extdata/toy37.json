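{
  "meta": {
    "name": "toy37",
    "RT": 0.6163
  },
  "stack": {
    "AU/AU": -2,
    "AU/UA": -2,
    "AU/CG": -2.5,
    "AU/GC": -2.5,
    "AU/GU": -1.5,
    "AU/UG": -1.5,
    "UA/AU": -2,
    "UA/UA": -2,
    "UA/CG": -2.5,
    "UA/GC": -2.5,
    "UA/GU": -1.5,
    "UA/UG": -1.5,
    "CG/AU": -2.5,
    "CG/UA": -2.5,
    "CG/CG": -3,
    "CG/GC": -3,
    "CG/GU": -2,
    "CG/UG": -2,
    "GC/AU": -2.5,
    "GC/UA": -2.5,
    "GC/CG": -3,
    "GC/GC": -3,
    "GC/GU": -2,
    "GC/UG": -2,
    "GU/AU": -1.5,
    "GU/UA": -1.5,
    "GU/CG": -2,
    "GU/GC": -2,
    "GU/GU": -1,
    "GU/UG": -1,
    "UG/AU": -1.5,
    "UG/UA": -1.5,
    "UG/CG": -2,
    "UG/GC": -2,
    "UG/GU": -1,
    "UG/UG": -1
  },
  "hairpin_len": [99, 99, 99, 5.4, 5.71, 5.95, 6.15, 6.32, 6.46, 6.59, 6.7, 6.8, 6.9, 6.98, 7.06, 7.14, 7.21, 7.27, 7.34, 7.39, 7.45, 7.5, 7.55, 7.6, 7.65, 7.69, 7.73, 7.77, 7.81, 7.85, 7.89],
  "bulge_len": [99, 3.8, 4.55, 4.99, 5.3, 5.54, 5.74, 5.9, 6.05, 6.17, 6.29, 6.39, 6.48, 6.57, 6.65, 6.72, 6.79, 6.86, 6.92, 6.98, 7.04, 7.09, 7.14, 7.19, 7.23, 7.28, 7.32, 7.36, 7.4, 7.44, 7.47],
  "internal_len": [99, 99, 4, 4.44, 4.75, 4.99, 5.19, 5.35, 5.5, 5.62, 5.74, 5.84, 5.94, 6.02, 6.1, 6.18, 6.25, 6.31, 6.37, 6.43, 6.49, 6.54, 6.59, 6.64, 6.68, 6.73, 6.77, 6.81, 6.85, 6.89, 6.92],
  "multiloop": {
    "a": 3.4,
    "b": 0.4,
    "c": 0.1
  },
  "terminal_au": 0.5,
  "ln_coeff": 1.08
}
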