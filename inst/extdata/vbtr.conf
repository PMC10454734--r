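# engine defaults
lambda = 0.5
mode = literal
tau = 0
alpha = 0.25
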