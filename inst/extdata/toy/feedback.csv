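USUBJID,MODULE,ITEM,RATING
T01,functional_analysis,effectiveness,3
T01,functional_analysis,novelty,2
T01,functional_analysis,applicability,4
T01,functional_analysis,navigation,3
T01,functional_analysis,enjoyability,2
T01,functional_analysis,relatability,1
T01,assertive_communication,novelty,
T02,coping_with_craving,effectiveness,3
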