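[
  {
    "label": "blind_tetra_dark",
    "note": "midwater tetra assayed in darkness; shear range typical of blunt turbulent channel profiles",
    "rho": {"type": "point", "value": 0.05},
    "eps": {"type": "interval", "lower": 0.01, "upper": 0.1},
    "alpha": {"type": "interval", "lower": 0, "upper": 0.17},
    "kappa": null,
    "beta": null,
    "alpha_estimated": false
  },
  {
    "label": "blind_cavefish",
    "note": "blind cavefish with indistinguishable thresholds between intact and ablated lateral line; swimming speed ~5 cm/s in still water used for alpha",
    "rho": {"type": "point", "value": 0.04},
    "eps": {"type": "interval", "lower": 0.01, "upper": 0.1},
    "alpha": {"type": "interval", "lower": 0, "upper": 0.16},
    "kappa": {"type": "point", "value": 0},
    "beta": {"type": "interval", "lower": 0, "upper": 100},
    "alpha_estimated": false
  },
  {
    "label": "ll_ablation_pair",
    "note": "paired studies with strong threshold increase after lateral line ablation; alpha estimated from intact-fish swimming speed",
    "rho": {"type": "point", "value": 0.1},
    "eps": {"type": "interval", "lower": 0.01, "upper": 0.1},
    "alpha": {"type": "interval", "lower": 0, "upper": 0.32},
    "kappa": {"type": "interval", "lower": 2, "upper": 7},
    "beta": {"type": "interval", "lower": 0, "upper": 256},
    "alpha_estimated": true
  },
  {
    "label": "mexican_tetra",
    "note": "Mexican tetra, body length 8.3 cm in a 25 cm channel (rho = 0.2*8.3/25); alpha estimated from intact-fish swimming speed",
    "rho": {"type": "point", "value": 0.066},
    "eps": {"type": "interval", "lower": 0.01, "upper": 0.1},
    "alpha": {"type": "interval", "lower": 0, "upper": 0.24},
    "kappa": {"type": "point", "value": 0},
    "beta": {"type": "interval", "lower": 0, "upper": 55},
    "alpha_estimated": true
  },
  {
    "label": "larvae_jet",
    "note": "larvae near the center of a submerged jet; strong local shear",
    "rho": {"type": "point", "value": 0.04},
    "eps": {"type": "point", "value": 1},
    "alpha": {"type": "point", "value": 1.3},
    "kappa": null,
    "beta": null,
    "alpha_estimated": false
  },
  {
    "label": "zebrafish_larvae",
    "note": "zebrafish larvae (~4.2 mm) in low-Reynolds tube flow, channel widths 1.27-4.76 cm; large velocity gradients",
    "rho": {"type": "interval", "lower": 0.018, "upper": 0.066},
    "eps": {"type": "interval", "lower": 0.2, "upper": 0.82},
    "alpha": null,
    "kappa": null,
    "beta": null,
    "alpha_estimated": false
  },
  {
    "label": "larvae_laminar_tube",
    "note": "larval fish in a narrow laminar tube; near-parabolic profile",
    "rho": {"type": "point", "value": 0.044},
    "eps": {"type": "point", "value": 1},
    "alpha": null,
    "kappa": null,
    "beta": null,
    "alpha_estimated": false
  },
  {
    "label": "larvae_shear_range",
    "note": "larval fish across laminar-to-blunt profiles",
    "rho": {"type": "point", "value": 0.018},
    "eps": {"type": "interval", "lower": 0.1, "upper": 1},
    "alpha": null,
    "kappa": null,
    "beta": null,
    "alpha_estimated": false
  },
  {
    "label": "benthic_channel",
    "note": "benthic species in a channel with possible bottom contact; alpha estimated from intact-fish swimming speed",
    "rho": {"type": "interval", "lower": 0.055, "upper": 0.127},
    "eps": {"type": "interval", "lower": 0.01, "upper": 0.1},
    "alpha": {"type": "interval", "lower": 0, "upper": 0.32},
    "kappa": {"type": "point", "value": 0},
    "beta": {"type": "interval", "lower": 0, "upper": 106},
    "alpha_estimated": true
  }
]
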