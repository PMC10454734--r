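"Index","AuthorYear","Title","Finding","Link"
1,"Durrani/2020","Controversies Regarding Ovarian Suppression and Infertility in Early Stage Breast Cancer","The main concern after adjuvant chemotherapy is the risk of losing fertility, as chemotherapy can induce early menopause in most premenopausal breast cancer patients. Tamoxifen only slightly increases the risk of early menopause.","32104064/"
2,"Castel/2013","Time course of arthralgia among women initiating aromatase inhibitor therapy and a postmenopausal comparison group in a prospective cohort","Women undergoing endocrine therapy have more severe joint pain, and they have more severe menopausal symptoms or existing joint-related diseases relative to before treatment. Joint pain is more severe than expected after menopause and often leads to reduced compliance.","23575918/"
3,"Rachner/2018","Bone health during endocrine therapy for cancer","Common osteoporosis guidelines are likely to have underestimated the fracture risk of patients receiving endocrine therapy-especially in patients on aromatase inhibitor therapy.","29572126/"
4,"Jankowitz/2013","Optimal systemic therapy for premenopausal women with hormone receptor-positive breast cancer","Chemotherapy has a shorter duration compared to endocrine therapy.","26996100/"
5,"Murray/2006","Neoadjuvant endocrine therapy models","Chemotherapy is more effective than endocrine therapy at shrinking the tumor.","16491621/"
6,"Collier/1997","New aromatase inhibitors for breast cancer","Endocrine therapy can provide self-administered oral medication, while chemotherapy requires injections at the hospital.","9282426/"
7,"Kanti/2015","Evaluation of trichodynia (hair pain) during chemotherapy or tamoxifen treatment in breast cancer patients","Chemotherapy has more severe hair loss and scalp pain compared to Tamoxifen, and the duration is also longer.","26403680/"
8,"Reinert/2018","Current Status of Neoadjuvant Endocrine Therapy in Early Stage Breast Cancer","Endocrine therapy is a practical, cost-effective treatment.","29663173/"
9,"Lima/2017","Temporal influence of endocrine therapy with tamoxifen and chemotherapy on nutritional risk and obesity in breast cancer patients","Women on endocrine therapy with TMX are mostly overweight and obese, most evidently in women who received CT and those who were at the beginning of treatment.","28851304/"
10,"Desai/2021","Breast Cancer in Women Over 65 years-a Review of Screening and Treatment Options","Primary endocrine therapy is a low-risk option for those with limited life expectancy.","34600726/"
11,"Brown/2020","Post-traumatic stress disorder and breast cancer: Risk factors and the role of inflammation and endocrine function","Tamoxifen also has been shown to be involved in adverse mood reactions such as depression.","32374431/"
12,"Huang/2023","Cost-effectiveness analysis of ovarian function preservation with GnRH agonist during chemotherapy in premenopausal women with early breast cancer","GnRHa plus Chemo was a cost-effective strategy for premenopausal women with BC in the USA.","37075316/"
13,"Eills/2006","Initial versus sequential adjuvant aromatase inhibitor therapy: a review of the current data","For those with positive nodes, the initiation of treatment with aromatase inhibitors may be beneficial to avoid tamoxifen-associated early relapses after diagnosis.","17257462/"
14,"Eills/2006","Initial versus sequential adjuvant aromatase inhibitor therapy: a review of the current data","From an economic perspective, aromatase inhibitors are considered cost-effective compared to tamoxifen.","17257462/"
15,"Lee/2019","Association between C-reactive protein and radiotherapy-related pain in a tri-racial/ethnic population of breast cancer patients: a prospective cohort study","In the postoperative radiotherapy process of obese patients, pain occurs, which has a negative impact on the quality of life.","31138314/"
16,"Hodis/2008","Postmenopausal hormone therapy and cardiovascular disease in perspective","Hormone therapy after menopause can reduce the mortality rate and the risk of coronary heart disease.","18677151/"
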