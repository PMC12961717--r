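age_min,age_max,sex,weight
65,69,F,0.35
65,69,M,0.40
70,74,F,0.40
70,74,M,0.45
75,79,F,0.45
75,79,M,0.50
80,84,F,0.55
80,84,M,0.60
85,130,F,0.70
85,130,M,0.75
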