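"Index","Condition","Value","Support","Oppose","Weight","SourceIndex"
1,"premenopausal","pregnancy later","Endocrine therapy","Chemotherapy",2,1
2,"-","pain","-","Endocrine therapy",2,2
3,"-","fracture","-","Endocrine therapy",2,3
4,"ER+, pre-surgery","treatment duration","Chemotherapy","Endocrine therapy",2,4
5,"premenopausal","treatment outcome","Chemotherapy","Endocrine therapy",3,5
6,"ER+, HER2-","convenience","Endocrine therapy","Chemotherapy",3,6
7,"-","appearance","Endocrine therapy","Chemotherapy",2,7
8,"ER+, Grade 2","cost","Endocrine therapy","-",2,8
9,"-","weight","-","Endocrine therapy",2,9
10,"ER+, age > 65","risk","-","Endocrine therapy",2,10
11,"ER+","depression","-","Endocrine therapy",2,11
12,"age 18–49, premenopausal","family cost effective","Chemotherapy+ GnRHa","Chemotherapy",3,12
13,"node-positive","recurrence","Anastrozole","Tamoxifen",2,13
14,"-","cost effective","Aromatase","Tamoxifen",2,14
15,"age < 50, after surgery, overweight","pain","-","Radiotherapy",2,15
16,"postmenopausal","mobility, survival","-","Hormone therapy",2,16
17,"ER+","risk","Endocrine therapy","Chemotherapy",2,5
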