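gender,age_band,events,person_years
ALL,ALL,2,72293
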