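"id","r1","r2","r3","structure","ec50_uM","pec50","split","pred_mlr","pred_comfa"
"1","3-carboxyphenyl","H","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)ccc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.28,6.553,"train",6.784,6.704
"2","3-carboxyphenyl","H","4-(trifluoromethyl)phenyl","O=C(Nc1cc(C(O)=O)ccc1)c1ccccc1Sc1ccc(C(F)(F)F)cc1",6.9,5.161,"test",5.653,5.171
"3","3-carboxyphenyl","H","4-bromophenyl","O=C(Nc1cc(C(O)=O)ccc1)c1ccccc1Sc1ccc(Br)cc1",3.7,5.432,"train",5.451,5.485
"4","3-carboxyphenyl","H","benzo[d][1,3]dioxol-5-yl","O=C(Nc1cc(C(O)=O)ccc1)c1ccccc1Sc1ccc2OCOc2c1",10,5,"train",5.336,5.133
"5","3-carboxyphenyl","H","2,3-dihydrobenzo[b][1,4]dioxin-6-yl","O=C(Nc1cc(C(O)=O)ccc1)c1ccccc1Sc1ccc2OCCOc2c1",4.9,5.31,"test",5.714,5.133
"6","3-carboxyphenyl","H","3-fluoro-4-(trifluoromethyl)phenyl","O=C(Nc1cc(C(O)=O)ccc1)c1ccccc1Sc1cc(F)c(C(F)(F)F)cc1",5,5.301,"train",5.232,5.358
"7","3-carboxyphenyl","H","styryl","O=C(Nc1cc(C(O)=O)ccc1)c1ccccc1SC=Cc1ccccc1",5.2,5.284,"test",4.85,5.639
"8","3-acetylphenyl","H","4-tert-butylphenyl","O=C(Nc1cc(C(C)=O)ccc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.48,6.319,"train",6.592,6.775
"9","3-cyanophenyl","H","4-tert-butylphenyl","O=C(Nc1cc(C#N)ccc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.23,6.638,"train",6.619,6.506
"10","3-methoxyphenyl","H","4-tert-butylphenyl","O=C(Nc1cc(OC)ccc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.38,6.42,"train",6.661,6.327
"11","3-(methylthio)phenyl","H","4-tert-butylphenyl","O=C(Nc1cc(SC)ccc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.2,6.699,"train",6.616,6.655
"12","3-(1H-tetrazol-5-yl)phenyl","H","4-tert-butylphenyl","O=C(Nc1cc(-c2nnn[nH]2)ccc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",2.9,5.538,"train",5.854,5.695
"13","3-carbamoylphenyl","H","4-tert-butylphenyl","O=C(Nc1cc(C(N)=O)ccc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.074,7.131,"train",7.203,7.099
"14","3,4-dimethoxyphenyl","H","4-tert-butylphenyl","O=C(Nc1cc(OC)c(OC)cc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.071,7.149,"test",7.771,6.606
"15","3-(carboxymethyl)phenyl","H","4-tert-butylphenyl","O=C(Nc1cc(CC(O)=O)ccc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.42,6.377,"train",6.493,6.414
"16","3-(2-carboxyethyl)phenyl","H","4-tert-butylphenyl","O=C(Nc1cc(CCC(O)=O)ccc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.064,7.194,"train",7.143,6.999
"17","2-methyl-3-carboxyphenyl","H","4-tert-butylphenyl","O=C(Nc1c(C)c(C(O)=O)ccc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.042,7.377,"train",7.115,7.266
"18","2-methoxy-5-carboxyphenyl","H","4-tert-butylphenyl","O=C(Nc1c(OC)ccc(C(O)=O)c1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",4.7,5.328,"train",5.307,5.444
"19","2-fluoro-5-carboxyphenyl","H","4-tert-butylphenyl","O=C(Nc1c(F)ccc(C(O)=O)c1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.48,6.319,"train",6.148,6.361
"20","2-chloro-5-carboxyphenyl","H","4-tert-butylphenyl","O=C(Nc1c(Cl)ccc(C(O)=O)c1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",1.1,5.959,"test",6.569,5.759
"21","3-carboxy-4-methylphenyl","H","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)c(C)cc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.045,7.347,"train",7.209,6.934
"22","3-carboxy-4-methoxyphenyl","H","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)c(OC)cc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.047,7.328,"test",7.65,7.563
"23","3-carboxy-4-chlorophenyl","H","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)c(Cl)cc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.28,6.553,"train",6.845,6.931
"24","3-carboxy-4-bromophenyl","H","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)c(Br)cc1)c1ccccc1Sc1ccc(C(C)(C)C)cc1",0.15,6.824,"train",6.937,6.889
"25","3-carboxyphenyl","chloro","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)ccc1)c1ccc(Cl)cc1Sc1ccc(C(C)(C)C)cc1",0.047,7.328,"train",6.862,6.868
"26","4-carboxymethylphenyl","H","naphthalen-2-yl","O=C(Nc1ccc(CC(O)=O)cc1)c1ccccc1Sc1ccc2ccccc2c1",3.1,5.509,"test",5.492,5.082
"27","3-carboxy-4-methylphenyl","methyl","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)c(C)cc1)c1ccc(C)cc1Sc1ccc(C(C)(C)C)cc1",0.043,7.367,"train",7.048,7.51
"28","3-carboxyphenyl","methyl","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)ccc1)c1ccc(C)cc1Sc1ccc(C(C)(C)C)cc1",0.061,7.215,"train",7.334,6.942
"29","3-carboxyphenyl","bromo","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)ccc1)c1ccc(Br)cc1Sc1ccc(C(C)(C)C)cc1",0.048,7.319,"train",7.16,7.241
"30","3-carboxyphenyl","methoxy","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)ccc1)c1ccc(OC)cc1Sc1ccc(C(C)(C)C)cc1",0.008,8.097,"train",7.888,8.175
"31","3-carboxy-4-methylphenyl","chloro","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)c(C)cc1)c1ccc(Cl)cc1Sc1ccc(C(C)(C)C)cc1",0.11,6.959,"train",7.178,7.027
"32","3-carboxy-4-methylphenyl","methoxy","4-tert-butylphenyl","O=C(Nc1cc(C(O)=O)c(C)cc1)c1ccc(OC)cc1Sc1ccc(C(C)(C)C)cc1",0.087,7.06,"test",7.861,6.858
"33","3-carboxypropyl","H","4-ethylphenyl","O=C(NCCCC(O)=O)c1ccccc1Sc1ccc(CC)cc1",5.8,5.237,"train",5.058,5.253
"34","3-carboxypropyl","H","4-tert-butylphenyl","O=C(NCCCC(O)=O)c1ccccc1Sc1ccc(C(C)(C)C)cc1",2.5,5.602,"train",5.748,5.885
"35","3-carboxypropyl","H","naphthalen-2-yl","O=C(NCCCC(O)=O)c1ccccc1Sc1ccc2ccccc2c1",8.6,5.066,"train",4.598,4.817
"36","4-carboxybutyl","H","naphthalen-2-yl","O=C(NCCCCC(O)=O)c1ccccc1Sc1ccc2ccccc2c1",8.3,5.081,"train",5.086,4.795
"37","3-methoxy-3-oxopropyl","H","naphthalen-2-yl","O=C(NCCC(=O)OC)c1ccccc1Sc1ccc2ccccc2c1",7.1,5.149,"test",5.377,4.857
"38","5-carboxypentyl","H","naphthalen-2-yl","O=C(NCCCCCC(O)=O)c1ccccc1Sc1ccc2ccccc2c1",4.4,5.357,"train",5.657,5.416
"39","4-carboxyphenyl","H","naphthalen-2-yl","O=C(Nc1ccc(C(O)=O)cc1)c1ccccc1Sc1ccc2ccccc2c1",1,6,"train",5.882,5.902
"40","3-carboxyphenyl","H","naphthalen-2-yl","O=C(Nc1cc(C(O)=O)ccc1)c1ccccc1Sc1ccc2ccccc2c1",1.5,5.824,"train",5.75,5.99
"41","4-carboxybenzyl","H","naphthalen-2-yl","O=C(NCc1ccc(C(O)=O)cc1)c1ccccc1Sc1ccc2ccccc2c1",1.3,5.886,"test",6.722,5.405
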