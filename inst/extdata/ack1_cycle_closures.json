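{
  "description": "Reported thermodynamic cycle closures (kcal/mol, mean +/- sigma) for the ACK1 inhibitor benchmark under set-up protocols A-E. Protocol E was not run for the charged batch (missing entries).",
  "units": "kcal/mol",
  "threshold": 0.8,
  "cycles": [
    {"cycle": "3-2-5-6", "closures": {"A": {"value": 0.6, "sigma": 0.3}, "B": {"value": 0.0, "sigma": 0.3}, "C": {"value": 0.6, "sigma": 0.6}, "D": {"value": 0.2, "sigma": 0.4}, "E": {"value": 0.8, "sigma": 0.3}}},
    {"cycle": "3-2-5", "closures": {"A": {"value": 0.2, "sigma": 0.2}, "B": {"value": -0.4, "sigma": 0.2}, "C": {"value": 0.7, "sigma": 0.5}, "D": {"value": 0.0, "sigma": 0.1}, "E": {"value": 0.5, "sigma": 0.3}}},
    {"cycle": "2-6-5", "closures": {"A": {"value": -0.8, "sigma": 0.4}, "B": {"value": 0.0, "sigma": 0.3}, "C": {"value": 0.0, "sigma": 0.3}, "D": {"value": -0.2, "sigma": 0.3}, "E": {"value": -0.7, "sigma": 0.8}}},
    {"cycle": "3-5-6", "closures": {"A": {"value": 0.4, "sigma": 0.2}, "B": {"value": 0.4, "sigma": 0.2}, "C": {"value": -0.1, "sigma": 0.4}, "D": {"value": 0.2, "sigma": 0.4}, "E": {"value": 0.4, "sigma": 0.1}}},
    {"cycle": "3-6-2", "closures": {"A": {"value": 0.2, "sigma": 0.4}, "B": {"value": 0.1, "sigma": 0.3}, "C": {"value": -0.6, "sigma": 0.5}, "D": {"value": 0.0, "sigma": 0.2}, "E": {"value": -0.1, "sigma": 0.9}}},
    {"cycle": "3-4-7-6", "closures": {"A": {"value": 1.0, "sigma": 0.4}, "B": {"value": 0.3, "sigma": 0.4}, "C": {"value": 1.6, "sigma": 0.4}, "D": {"value": 0.2, "sigma": 0.4}, "E": {"value": 0.3, "sigma": 0.7}}},
    {"cycle": "3-7-6", "closures": {"A": {"value": 0.2, "sigma": 0.4}, "B": {"value": 0.1, "sigma": 0.3}, "C": {"value": 0.9, "sigma": 0.7}, "D": {"value": 0.2, "sigma": 0.3}, "E": {"value": -0.2, "sigma": 0.9}}},
    {"cycle": "4-6-7", "closures": {"A": {"value": 0.9, "sigma": 0.6}, "B": {"value": 0.0, "sigma": 0.3}, "C": {"value": -1.1, "sigma": 0.5}, "D": {"value": 0.2, "sigma": 0.3}, "E": {"value": -0.2, "sigma": 0.8}}},
    {"cycle": "3-4-7", "closures": {"A": {"value": 0.8, "sigma": 0.4}, "B": {"value": 0.2, "sigma": 0.4}, "C": {"value": 0.7, "sigma": 0.7}, "D": {"value": 0.0, "sigma": 0.2}, "E": {"value": 0.5, "sigma": 0.5}}},
    {"cycle": "3-4-6", "closures": {"A": {"value": 1.9, "sigma": 0.4}, "B": {"value": 0.3, "sigma": 0.2}, "C": {"value": 0.5, "sigma": 0.5}, "D": {"value": 0.2, "sigma": 0.4}, "E": {"value": 0.1, "sigma": 0.4}}},
    {"cycle": "45-16-44", "closures": {"A": {"value": -2, "sigma": 1}, "B": {"value": -3, "sigma": 1}, "C": {"value": -2, "sigma": 1}, "D": {"value": -1.8, "sigma": 0.9}, "E": null}},
    {"cycle": "38-39-35-36", "closures": {"A": {"value": 0.6, "sigma": 0.5}, "B": {"value": 0.6, "sigma": 0.5}, "C": {"value": 0.2, "sigma": 0.3}, "D": {"value": 0.2, "sigma": 0.3}, "E": null}}
  ]
}
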