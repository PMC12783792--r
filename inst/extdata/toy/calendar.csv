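USUBJID,ADT,DRINK
T01,2022-03-01,0
T01,2022-03-02,0
T01,2022-03-03,0
T01,2022-03-04,0
T01,2022-03-05,1
T01,2022-03-06,0
T01,2022-03-07,0
T01,2022-03-08,1
T01,2022-03-09,0
T01,2022-03-10,0
T01,2022-03-11,1
T01,2022-03-12,0
T01,2022-03-13,0
T01,2022-03-14,0
T01,2022-03-16,0
T01,2022-03-17,1
T02,2022-03-10,0
T02,2022-03-11,0
T02,2022-03-12,0
T02,2022-03-13,0
T02,2022-03-14,0
T02,2022-03-15,0
T02,2022-03-16,0
T02,2022-03-17,0
T02,2022-03-18,1
T02,2022-03-19,0
T02,2022-03-20,0
T03,2022-03-08,0
T03,2022-03-09,
T03,2022-03-10,0
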