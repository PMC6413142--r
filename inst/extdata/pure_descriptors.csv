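component_id,smiles,RBN,MAXDP,Psi_i_0,SpMax4_Bh(e),Mor24u,Mor16m
methane,C,0,0.00000000000000000,1.0000000000000000,0.00000000000000000,0.0000000000000000000,0.0000000000000000000
ethane,CC,0,0.00000000000000000,1.4142135623730951,0.00000000000000000,-0.0112042940343156892,-0.0317322261422914448
propane,CCC,0,0.12500000000000000,2.2307101433008212,0.00000000000000000,-0.0133911763130874460,-0.0755532067236094895
butane,CCCC,1,0.18055555555555555,3.0472067242285474,0.83881463511376064,-0.0133909188047487658,-0.1190147421185056564
isobutane,CC(C)C,0,0.16666666666666669,2.9873457473440812,0.82779203251582179,-0.0065606468363126336,-0.1314629417439524550
ethylene,C=C,0,0.00000000000000000,1.1547005383792515,0.00000000000000000,-0.0223751840463834936,0.0455670676625636803
propylene,CC=C,0,0.36111111111111110,1.9915638315627209,0.00000000000000000,-0.0280396003716697345,-0.0016225527411688201
butylene,CCC=C,1,0.47916666666666663,2.8080604124904469,0.81580669971958208,-0.0233375241133933313,-0.0501703661809817514
butadiene,C=CC=C,1,0.36111111111111110,2.5689141007523464,0.80060941168923616,-0.0572552894904238968,0.0453896676385750000
acetylene,C#C,0,0.00000000000000000,1.0000000000000000,0.00000000000000000,0.0220830892092386856,-0.0412508086836371260
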