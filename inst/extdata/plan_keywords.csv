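"Category","Keyword"
"Endocrine therapy","Hormone therapy"
"Endocrine therapy","Tamoxifen"
"Endocrine therapy","Aromatase inhibitors"
"Endocrine therapy","Ovarian ablation/suppression"
"Radiotherapy","-"
"Chemotherapy","-"
"Surgery","Mastectomy"
"Surgery","Breast reconstruction"
"Surgery","Breast conservation"
"Targeted Therapy","-"
"Immunotherapy","-"
"Bisphosphonates","-"
"Complementary Therapy","-"
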