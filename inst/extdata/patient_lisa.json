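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
  "occupation": "Actor",
  "values": {
    "pregnancy later": 0.95,
    "treatment duration": 0.9,
    "appearance": 0.9,
    "convenience": 0.7,
    "pain": 0.2
  }
}
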