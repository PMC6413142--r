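component_id,smiles,RBN,MAXDP,Psi_i_0,SpMax4_Bh(e),Mor24u,Mor16m
methane,C,0,0.0,1.0,0.0,0.0,0.0
ethane,CC,0,0.0,1.4142135623730951,0.0,-0.011,-0.032
propane,CCC,0,0.125,2.230710143300821,0.0,-0.013,-0.076
butane,CCCC,1,0.18055555555555536,3.047206724228547,0.8388146351137606,-0.013,-0.119
isobutane,CC(C)C,0,0.16666666666666652,2.987345747344081,0.8277920325158218,-0.007,-0.131
ethylene,C=C,0,0.0,1.1547005383792515,0.0,-0.022,0.046
propylene,CC=C,0,0.36111111111111116,1.9915638315627209,0.0,-0.028,-0.002
butylene,CCC=C,1,0.4791666666666665,2.808060412490447,0.8158066997195821,-0.023,-0.05
butadiene,C=CC=C,1,0.36111111111111116,2.5689141007523464,0.8006094116892362,-0.057,0.045
acetylene,C#C,0,0.0,1.0,0.0,0.022,-0.041
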