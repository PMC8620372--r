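gender,age_band,doses
ALL,<50,935449
F,50-59,350064
F,60-69,215887
F,70-79,404790
F,80+,36940
M,50-59,228011
M,60-69,148207
M,70-79,358223
M,80+,25159
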