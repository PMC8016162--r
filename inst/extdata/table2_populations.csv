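state,boundaries,AMBER-KK,AMBER-KWK,CHARMM-KK,CHARMM-KWK
I,,97.8,43.2,52.3,2.7
II,S4-S3,,11.0,0.7,35.5
II',S4-S3,,4.6,0.3,11.6
III,S3-S2,,16.6,7.1,
IV,S2-S1,,8.5,4.0,
V,S4-S3+S3-S2,,0.4,0.2,4.8
VI,S3-S2+S1-S0,,13.3,10.3,
VII,S3-S2+S2-S1+S1-S0,,,7.6,0.7
other,,2.2,2.4,17.5,44.7
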