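specimen_id,sex,age_class,fdi_code,ba_code
Sp17,F,20-39,15,URP4
Sp20,I,>20,35,LLP4
Sp39,F,20-49,35,LLP4
Sp114,F,20-60,14,URP3
Sp173,M,>60,45,LRP4
Sp199,M,>30,11,URI1
Sp199,M,>30,12,URI2
Sp335,M,>18,13,URC
Sp335,M,>18,23,ULC
Sp479,M,20-60,11,URI1
Sp583,F,>60,45,LRP4
Sp591,M,20-39,12,URI2
Sp666,M,>30,33,LLC
Sp709,I,>20,31,LLI1
Sp735,M,>20,45,LRP4
Sp755,F,20-39,13,URC
Sp755,F,20-39,23,ULC
Sp810,F,>20,13,URC
Sp810,F,>20,23,ULC
Sp876,M,>30,45,LRP4
Sp876,M,>30,35,LLP4
Sp876,M,>30,44,LRP3
Sp884,F,>30,34,LLP3
Sp884,F,>30,35,LLP4
Sp914,M,20-39,33,LLC
Sp914,M,20-39,34,LLP3
Sp914,M,20-39,35,LLP4
Sp914,M,20-39,43,LRC
Sp1010,M,>30,44,LRP3
Sp1135,M,>30,11,URI1
Sp1172,F,>30,15,URP4
Sp1172,F,>30,24,ULP3
Sp1230,M,>20,34,LLP3
Sp1230,M,>20,44,LRP4
Sp1300,MD,MD,14,URP3
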