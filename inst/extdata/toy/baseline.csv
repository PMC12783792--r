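USUBJID,STUDYID,AGE,SEX,ASIALC,RANDDT
T01,1,45,M,0.42,2022-03-07
T02,2,30,F,,2022-03-07
T03,1,19,M,0,2022-03-08
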