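tooth_id,ba_printed,group,wear_deg,wear_dir,wear_for,caries_si,caries_sta,pulp_exp,impacted,hc,fen,cal,nt,ant,max_thi_um,loc_max,loc_min,pref,shape_note,topo_loc,max_ve_um,aspect,topo_note,of_loc,of_max_ve_um,of_aspect,of_note,excluded
Sp755_13,URL,IMP,1,1,1,,,0,1,3.3.m,0,0,-,-,1000,2d,<,Yes,Nds (d),2d,690,+S2,Nds,2m,100,-R2,,0
Sp755_23,ULC,IMP,1,1,1,,,0,1,3.3.m,0,0,-,-,1070,2d,<,Yes,NOD (d),2d,450,+S2,IL,2m,90,-R2,IL,0
Sp114_14,URP3,INF,NA,NA,NA,1,4,M,0,3.4.M,1,0,0,1,1470,m,<,No,OG,m,475,+S2,,,,,,0
Sp335_23,ULC,INF,NA,NA,NA,1,4,M,0,1.4.M,1,0,2,1,2160,<,>,No,RES (>),<,250,+R2,,,,,,0
Sp914_43,LRC,INF,NA,NA,NA,1,4,M,0,1.4.m,0,0,0,NA,1950,d,m,No,,d,450,+S2,,,,,,0
Sp1172_15,URP4,INF,NA,NA,NA,1,4,M,0,1.4.M,0,0,1d,1,1380,d,No,No,RES (d),d,110,-S2,AF,m,220,-S2,AF,0
Sp17_15,URP4,HYPO,3,4,2,,,0,0,1.2.m,0,0,1d,1,1640,2m,<,No,FR (2m),2m,160,-R2,FR,,,,,0
Sp20_35,LLP4,HYPO,2,6,2,,,0,0,1.2.m,0,0,0,1,1310,1m,<,No,,1m,180,-S2,IL,2d,150,+S2,CL,0
Sp173_45,LRP4,HYPO,3,6,3,,,0,0,1.2.m,0,0,0,2,1470,1>,<,No,SE,1>,170,-S1,CL,,,,,0
Sp914_34,LLP3,HYPO,2,1,1,,,0,0,1.2.m,0,0,0,NA,1410,1d,No,No,,1d,140,-S2,,,,,,0
Sp1230_34,LLP3,HYPO,3,1,1,,,0,0,1.2.m,0,1,0,1,1240,1m,No,No,,1m,110,-R2,,,,,,0
Sp1230_44,URP3,HYPO,3,1,1,,,0,0,1.2.M,0,0,0,1,1280,1d,m,No,2 roots,,,,,,,,,1
Sp39_35,LLP4,HYPER,8,4,2,,,0,0,1.2.m,0,0,2,1,740,1m,No,Yes,,1m,400,+R2,,,,,,0
Sp199_11,URI1,HYPER,6,6,4,,,0,0,1.2.m,0,0,0,1,1380,1>,<,Yes,RES (1<),1>,170,-R1,,,,,,0
Sp199_12,URI2,HYPER,6,4,4,,,0,0,1.3.m,0,0,0,1,900,1>,<,Yes,,1>,230,+R1,IL,1<,350,+R1,,0
Sp335_13,URC,HYPER,4,2,2,,,0,0,1.2.m,0,0,2,1,1970,1d,<,Yes,FR (1>m),1d,325,+R1,,,,,,0
Sp479_11,URI1,HYPER,7,2,2,,,0,0,3.2.M,0,0,0,1,1480,1>,<,Yes,NOD (m>),1m>,665,+S2,NOD,,,,,0
Sp591_12,URI2,HYPER,5,4,6,,,0,0,1.1.m,0,0,1d,1,1510,1>,<,Yes,FR (1>),1d,192,-R2,FR,,,,,0
Sp810_13,URC,HYPER,3,2,2,,,0,0,1.3.m,0,0,0,NA,1030,1>,<,Yes,,1>,200,+R1,,,,,,0
Sp810_23,ULC,HYPER,3,2,2,,,0,0,3.2.m,0,0,0,NA,790,2>,<,Yes,Nds (>),2>,475,+S2,Nds,,,,,0
Sp876_35,LLP4,HYPER,6,2,6,,,0,0,1.2.m,0,1,2,2,1010,1>,<,Yes,,1>,250,+R2,,,,,,0
Sp914_33,LLC,HYPER,4,4,4,,,0,0,1.2.m,0,0,0,NA,1270,1>,No,Yes,,1>,95,-R1,,,,,,0
Sp1010_44,LRP3,HYPER,5,4,6,,,0,0,3.2.M,0,0,1d,NA,2080,1d,m,Yes,2 roots,,,,,,,,,1
Sp1172_24,ULP3,HYPER,6,2,4,,,0,0,3.2.M,0,0,1d,1,1200,2d,<,Yes,NOD (d),,,,,,,,,0
Sp1135_11,URI1,HYPER,6,4,5,,,0,0,1.3.m,0,0,0,1,1180,1>d +2m,1<,Yes,RID (<),1m,300,+R1,,2<d,260,+R1,RID,0
Sp583_45,LRP4,MIX,6,4,2,,,0,0,3.2.M,0,1,1d,2,2770,1,<,Yes,LSP (1),2>,43,-S2,,,,,,0
Sp666_33,LLC,MIX,7,5,6,2,2,0,0,3.2.M,0,1,1m,NA,2350,1m,<,Yes,"NOD, CAR (m)",1m,475,+S2,NOD,,,,,0
Sp709_31,LLI1,MIX,6,6,4,,,0,0,3.1.m,0,1,0,NA,1330,1<,No,Yes,LSP (<),<,550,+R1,LSP,,,,,0
Sp735_45,LRP4,MIX,4,6,3,2,4,C,0,1.2.M,0,0,1d,2,1230,1m,No,Yes,CAR (m),1m,175,-R1,,d,118,-S2,IL,0
Sp876_44,LRP3,MIX,NA,NA,NA,1,4,M,0,1.4.m,0,1,0,2,1320,1d,No,Yes,RES (m<),1d,200,+R2,,,,,,0
Sp876_45,LRP4,MIX,4,6,3,2,2,0,0,1.2.M,0,1,0,2,1670,1d,<,No,FR (1>),2d,200,+R2,,,,,,0
Sp884_34,LLP3,MIX,8,3,6,,,0,0,3.4.M,0,0,1m,1,1450,d,No,No,W,1d,370,+R2,,,,,,0
Sp884_35,LLP4,MIX,8,7,6,,,W,0,3.4.M,0,0,1d,2,1590,d>,<,Yes,OG (>),>,310,+R2,,,,,,0
Sp914_35,LLP4,MIX,3,3,3,2,3,0,0,1.2.m,0,0,0,NA,1100,1d,No,No,CAR (d),1d,375,+R2,,,,,,0
Sp1300_14,URP3,MIX,7,4,4,2,2,0,0,1.2.M,0,0,NA,2,1440,1m,>,No,CAR (m),2m,280,+R1,,,,,,0
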