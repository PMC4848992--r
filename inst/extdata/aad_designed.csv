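"id","headgroup","pos2","r2","r3","structure","pred_mlr_ref","pred_comfa_ref"
"T30","OH","H","OCH3","C(CH3)3","O=C(Nc1cc(C(=O)O)ccc1)c1ccc(OC)cc1Sc1ccc(C(C)(C)C)cc1",7.888,8.175
"N1","N(CH3)2","H","CH3","C(CF3)3","O=C(Nc1cc(C(=O)N(C)C)ccc1)c1ccc(C)cc1Sc1ccc(C(C(F)(F)F)(C(F)(F)F)C(F)(F)F)cc1",9.032,8.35
"N2","N(CH3)2","H","CH3","C(CH3)3","O=C(Nc1cc(C(=O)N(C)C)ccc1)c1ccc(C)cc1Sc1ccc(C(C)(C)C)cc1",8.274,8.323
"N3","N(CH3)2","H","OCH3","C(CH3)3","O=C(Nc1cc(C(=O)N(C)C)ccc1)c1ccc(OC)cc1Sc1ccc(C(C)(C)C)cc1",8.626,8.322
"N4","N(CH3)2","H","CH3","CI3","O=C(Nc1cc(C(=O)N(C)C)ccc1)c1ccc(C)cc1Sc1ccc(C(I)(I)I)cc1",8.744,8.304
"N5","N(CH3)2","OH","CH3","C(CH3)3","O=C(Nc1c(O)c(C(=O)N(C)C)ccc1)c1ccc(C)cc1Sc1ccc(C(C)(C)C)cc1",8.26,8.36
"N6","N(CH3)2","OH","CH3","CI3","O=C(Nc1c(O)c(C(=O)N(C)C)ccc1)c1ccc(C)cc1Sc1ccc(C(I)(I)I)cc1",8.828,8.357
"N7","N(CH3)2","CH3","CH3","C(CF3)3","O=C(Nc1c(C)c(C(=O)N(C)C)ccc1)c1ccc(C)cc1Sc1ccc(C(C(F)(F)F)(C(F)(F)F)C(F)(F)F)cc1",9.123,8.374
"N8","N(CH3)2","NH2","CH3","C(CF3)3","O=C(Nc1c(N)c(C(=O)N(C)C)ccc1)c1ccc(C)cc1Sc1ccc(C(C(F)(F)F)(C(F)(F)F)C(F)(F)F)cc1",8.816,8.378
"N9","N(CH3)2","OH","CH3","C(CF3)3","O=C(Nc1c(O)c(C(=O)N(C)C)ccc1)c1ccc(C)cc1Sc1ccc(C(C(F)(F)F)(C(F)(F)F)C(F)(F)F)cc1",9.024,8.388
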