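{
  "name": "model5",
  "components": [
    {
      "variable": "transductal_diameter",
      "kind": "numeric",
      "zero_score": 0,
      "bins": [
        {"from": 0, "to": 1.5, "score": 1},
        {"from": 1.5, "to": 3, "score": 2},
        {"from": 3, "to": null, "score": 3}
      ]
    },
    {
      "variable": "ductal_vmax_vmin_ratio",
      "kind": "numeric",
      "zero_score": 0,
      "bins": [
        {"from": 0, "to": 1.5, "score": 1},
        {"from": 1.5, "to": 2, "score": 2},
        {"from": 2, "to": null, "score": 3}
      ]
    },
    {
      "variable": "lpa_diastolic_velocity",
      "kind": "numeric",
      "zero_score": 0,
      "bins": [
        {"from": 0, "to": 30, "score": 1},
        {"from": 30, "to": 50, "score": 2},
        {"from": 50, "to": null, "score": 3}
      ]
    },
    {
      "variable": "dao_flow_direction",
      "kind": "categorical",
      "categories": {"forward": 0, "absent": 1, "reverse": 2}
    }
  ]
}
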