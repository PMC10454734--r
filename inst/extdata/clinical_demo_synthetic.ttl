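@prefix vbtr: <http://vbtr.example.org/ns#> .

vbtr:arg_c1
    a vbtr:Argument ;
    vbtr:disease "breast cancer" ;
    vbtr:condition "ER+" ;
    vbtr:plan "Endocrine therapy" ;
    vbtr:support_type "positive" ;
    vbtr:weight 3 ;
    vbtr:evidence_kind "clinical" .

vbtr:arg_c2
    a vbtr:Argument ;
    vbtr:disease "breast cancer" ;
    vbtr:condition "ER+" ;
    vbtr:plan "Chemotherapy" ;
    vbtr:support_type "positive" ;
    vbtr:weight 2 ;
    vbtr:evidence_kind "clinical" .

vbtr:arg_c3
    a vbtr:Argument ;
    vbtr:disease "breast cancer" ;
    vbtr:condition "HER2+" ;
    vbtr:plan "Targeted Therapy" ;
    vbtr:support_type "positive" ;
    vbtr:weight 3 ;
    vbtr:evidence_kind "clinical" .

vbtr:arg_c4
    a vbtr:Argument ;
    vbtr:disease "breast cancer" ;
    vbtr:condition "node-positive" ;
    vbtr:plan "Chemotherapy" ;
    vbtr:support_type "positive" ;
    vbtr:weight 2 ;
    vbtr:evidence_kind "clinical" .

vbtr:arg_c5
    a vbtr:Argument ;
    vbtr:disease "breast cancer" ;
    vbtr:condition "age > 70" ;
    vbtr:plan "Chemotherapy" ;
    vbtr:support_type "negative" ;
    vbtr:weight 1 ;
    vbtr:evidence_kind "clinical" .

vbtr:arg_c6
    a vbtr:Argument ;
    vbtr:disease "breast cancer" ;
    vbtr:condition "postmenopausal, ER+" ;
    vbtr:plan "Aromatase inhibitors" ;
    vbtr:support_type "positive" ;
    vbtr:weight 2 ;
    vbtr:evidence_kind "clinical" .

vbtr:arg_c7
    a vbtr:Argument ;
    vbtr:disease "breast cancer" ;
    vbtr:condition "-" ;
    vbtr:plan "Complementary Therapy" ;
    vbtr:support_type "positive" ;
    vbtr:weight 1 ;
    vbtr:evidence_kind "clinical" .

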