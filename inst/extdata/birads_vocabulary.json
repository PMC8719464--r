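{
  "version": "1.0",
  "comment": "Controlled vocabulary and numeric codes for BI-RADS mass descriptions. Malignant, uncertain and benign findings are coded 1, 0.5 and 0.",
  "fields": ["shape", "margin_sharpness", "microlobulated", "spiculated", "density"],
  "codes": {
    "shape": {"oval": 0, "round": 0, "irregular": 1},
    "margin_sharpness": {"circumscribed": 0, "obscured": 0.5, "indistinct": 1},
    "microlobulated": {"no": 0, "yes": 1},
    "spiculated": {"no": 0, "yes": 1},
    "density": {"low": 0, "fat-containing": 0, "equal": 0.5, "high": 1}
  }
}
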