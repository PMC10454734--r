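"Item","ValueTerm"
"Weight gain","weight"
"Alopecia","appearance"
"Skin darkens","appearance"
"Diarrhea","unbearable"
"Memory loss","work"
"Tremor","work"
"Insomnia","rest"
"Fatigue","exhaustion"
"Joint pain","pain"
"Numbness in limbs","walking"
"Back pain","pain"
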