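dominant,subordinate
HCC_DM_SEVERE,HCC_DM_MILD
HCC_CKD_SEVERE,HCC_CKD_MILD
HCC_CANCER_ACTIVE,HCC_CANCER_REMISSION
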