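"Occupation","Related","Item","Weight"
"Actor","Appearance, Temperament","Weight gain",0.88
"Actor","Appearance, Temperament","Alopecia",0.85
"Actor","Appearance, Temperament","Skin darkens",0.74
"Actor","Appearance, Temperament","Diarrhea",0.3
"Writer","Creativity, Spirit","Memory loss",0.94
"Writer","Creativity, Spirit","Tremor",0.87
"Writer","Creativity, Spirit","Insomnia",0.81
"Writer","Creativity, Spirit","Fatigue",0.67
"Assembly line worker","Work and rest, Repetitive work","Joint pain",0.86
"Assembly line worker","Work and rest, Repetitive work","Insomnia",0.73
"Assembly line worker","Work and rest, Repetitive work","Numbness in limbs",0.7
"Assembly line worker","Work and rest, Repetitive work","Back pain",0.65
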