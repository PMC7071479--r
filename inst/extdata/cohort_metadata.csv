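case_id,sex,age,final_mmse,braak_stage,apoe
HT-05-13,M,70,25,II,e3/e3
HT-09-13,M,77,22,III,e3/e3
HT-11-13,F,55,23,I,e3/e4
HT-20-13,M,64,26,I,
HT-03-14,M,72,16,III,e3/e3
HT-13-13,F,80,13,VI,e3/e4
HT-14-13,F,84,13,VI,e3/e3
HT-06-14,M,77,6,VI,e3/e4
HT-10-14,M,68,7,VI,e4/e4
HT-14-14,M,55,0,VI,e3/e3
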