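{
  "meta": {
    "name": "toy37_alt",
    "RT": 0.6163
  },
  "stack": {
    "AU/AU": -1.75,
    "AU/UA": -1.75,
    "AU/CG": -2.25,
    "AU/GC": -2.25,
    "AU/GU": -1.25,
    "AU/UG": -1.25,
    "UA/AU": -1.75,
    "UA/UA": -1.75,
    "UA/CG": -2.25,
    "UA/GC": -2.25,
    "UA/GU": -1.25,
    "UA/UG": -1.25,
    "CG/AU": -2.25,
    "CG/UA": -2.25,
    "CG/CG": -3.15,
    "CG/GC": -3.15,
    "CG/GU": -1.75,
    "CG/UG": -1.75,
    "GC/AU": -2.25,
    "GC/UA": -2.25,
    "GC/CG": -3.15,
    "GC/GC": -3.15,
    "GC/GU": -1.75,
    "GC/UG": -1.75,
    "GU/AU": -1.25,
    "GU/UA": -1.25,
    "GU/CG": -1.75,
    "GU/GC": -1.75,
    "GU/GU": -0.75,
    "GU/UG": -0.75,
    "UG/AU": -1.25,
    "UG/UA": -1.25,
    "UG/CG": -1.75,
    "UG/GC": -1.75,
    "UG/GU": -0.75,
    "UG/UG": -0.75
  },
  "hairpin_len": [99, 99, 99, 5.7, 6.01, 6.25, 6.45, 6.62, 6.76, 6.89, 7, 7.1, 7.2, 7.28, 7.36, 7.44, 7.51, 7.57, 7.64, 7.69, 7.75, 7.8, 7.85, 7.9, 7.95, 7.99, 8.03, 8.07, 8.11, 8.15, 8.19],
  "bulge_len": [99, 4, 4.75, 5.19, 5.5, 5.74, 5.94, 6.1, 6.25, 6.37, 6.49, 6.59, 6.68, 6.77, 6.85, 6.92, 6.99, 7.06, 7.12, 7.18, 7.24, 7.29, 7.34, 7.39, 7.43, 7.48, 7.52, 7.56, 7.6, 7.64, 7.67],
  "internal_len": [99, 99, 4.2, 4.64, 4.95, 5.19, 5.39, 5.55, 5.7, 5.82, 5.94, 6.04, 6.14, 6.22, 6.3, 6.38, 6.45, 6.51, 6.57, 6.63, 6.69, 6.74, 6.79, 6.84, 6.88, 6.93, 6.97, 7.01, 7.05, 7.09, 7.12],
  "multiloop": {
    "a": 3.9,
    "b": 0.3,
    "c": 0.2
  },
  "terminal_au": 0.7,
  "ln_coeff": 1.08
}
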