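{
  "disease": "breast cancer",
  "facts": {
    "menopausal_status": "pre",
    "er": "positive",
    "her2": "negative",
    "age": 32,
    "grade": 2,
    "surgery_phase": "pre",
    "bmi_class": "normal"
  },
  "occupation": "Assembly line worker",
  "values": {
    "treatment outcome": 0.95,
    "cost": 0.9,
    "pain": 0.9,
    "cost effective": 0.85,
    "treatment duration": 0.2
  }
}
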