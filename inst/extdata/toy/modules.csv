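USUBJID,MODULE,COMPDT
T01,functional_analysis,2022-03-07
T01,assertive_communication,2022-03-11
T02,coping_with_craving,2022-03-14
T02,cognitive_restructuring,2022-03-14
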