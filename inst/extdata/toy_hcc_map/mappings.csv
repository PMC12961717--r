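code,category
E10,HCC_DM_SEVERE
E11,HCC_DM_MILD
E119,HCC_DM_MILD
I50,HCC_CHF
I509,HCC_CHF
N184,HCC_CKD_SEVERE
N185,HCC_CKD_SEVERE
N182,HCC_CKD_MILD
J44,HCC_COPD
J449,HCC_COPD
C50,HCC_CANCER_ACTIVE
C61,HCC_CANCER_ACTIVE
Z85,HCC_CANCER_REMISSION
F32,HCC_DEPRESSION
F33,HCC_DEPRESSION
E66,HCC_OBESITY
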