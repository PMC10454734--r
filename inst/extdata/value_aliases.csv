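"Alias","Target","Kind"
"pregnancy later","pregnancy","alias"
"cost","expensive","alias"
"mobility","walking","alias"
"treatment outcome","","extension"
"family cost effective","","extension"
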