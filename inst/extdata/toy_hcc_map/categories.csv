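category,weight
HCC_DM_SEVERE,0.50
HCC_DM_MILD,0.20
HCC_CHF,0.65
HCC_CKD_SEVERE,0.70
HCC_CKD_MILD,0.30
HCC_COPD,0.35
HCC_CANCER_ACTIVE,0.95
HCC_CANCER_REMISSION,0.40
HCC_DEPRESSION,0.25
HCC_OBESITY,0.15
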