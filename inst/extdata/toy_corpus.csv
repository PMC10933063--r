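id,year,text
T1,2020,fall ladder roof fall
T2,2020,fall stairs night
T3,2020,burn kitchen oil fall
T4,2020,bicycle road fall helmet
T5,2020,fall bathroom floor slip
T6,2020,assault street night fall
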