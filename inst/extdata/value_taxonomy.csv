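"Category","Term"
"Activities","fracture"
"Activities","recurrence"
"Activities","traveling"
"Activities","reading"
"Activities","walking"
"Abilities","survival"
"Abilities","work"
"Abilities","rest"
"Abilities","talking"
"Abilities","vision"
"Abilities","convenience"
"Abilities","exercise"
"Possessions","convenience"
"Possessions","transportation"
"Possessions","expensive"
"Possessions","cost effective"
"Principles","independence"
"Principles","treatment duration"
"Principles","confidence"
"Principles","appearance"
"Principles","weight"
"Emotions","risk"
"Emotions","pregnancy"
"Emotions","exhaustion"
"Emotions","pain"
"Emotions","unbearable"
"Emotions","depression"
"Relationships","family"
"Relationships","friend"
"Relationships","colleague"
"Relationships","community"
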