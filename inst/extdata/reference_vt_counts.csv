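gender,age_band,events,person_years
F,50-59,2,6405
F,60-69,10,13460
F,70-79,22,12802
F,80+,10,6275
M,50-59,5,6422
M,60-69,13,12393
M,70-79,15,10418
M,80+,6,4117
ALL,ALL,83,72293
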