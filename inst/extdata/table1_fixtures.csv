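name,source_index,reference_smiles,obtained_bigsmiles,corrected_bigsmiles,provenance,ends_implied
Poly(3-methoxypropylene oxide),28,*CC(COC)O*,"{<CC(OC)O>, <C(OC)CO>}","{<CC(COC)O>, <C(COC)CO>}",table1,FALSE
Perfluoropolymer (dodecafluoro methyltriazine),65,*c1nc(C)nc(C(F)(OC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)OC(*)C(F)(F)F)C(F)(F)F)n1,{<C(C(F)(F)F)OC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)OC(F)(C(F)(F)F)c1nc(nc(C)n1)>},{<c1nc(C)nc(n1)C(F)(C(F)(F)F)OC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)OC(C(F)(F)F)>},table1,FALSE
Perfluoropolymer (tetradecafluoro trifluoromethyltriazine),69,*C(C(F)(F)F)OC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)OC(C(F)(F)F)c1nc(nc(C(F)(F)F)n1)*,{<C(C(F)(F)F)OC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)OC(C(F)(F)F)c1nc(nc(C(F)(F)F)n)>},{<C(C(F)(F)F)OC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)OC(C(F)(F)F)c1nc(nc(C(F)(F)F)n1)>},table1,FALSE
Poly(vinyl butyrate),78,*CC(OC( = O)CCC)*,{$CC(OC( = O)CCC$},{$CC(OC( = O)CCC)$},table1,FALSE
Poly(isobutyl methacrylate),113,*CC(*)(C)C( = O)OCC(C)C,{$CC(C)(C( = O)CC(C)C)$},{$CC(C( = O)OCC(C)C)(C)$},table1,FALSE
Poly(cyclohexyl alpha-chloroacrylate),192,*CC(*)(Cl)C( = O)OC1CCCCC1,{$CC(C( = O)C1CCCCC1)(Cl)$},{$CC(C( = O)OC1CCCCC1)(Cl)$},table1,FALSE
Poly(N-vinyl carbazole),236,*CC(*)n1c2ccccc2c2ccccc21,{$CC(N1c2c(cccc2)c3c1(cccc3)$},{$CC(N1c2c(cccc2)c3ccccc13)$},table1,FALSE
"Poly(quinoxaline-2,7-diylquinoxaline-7,2-diyl-p-terphenyl-4,4-ylene)",283,*c1ccc(-c2ccc(-c3ccc(-c4cnc5ccc(-c6ccc7ncc(*)nc7c6)cc5n4)cc3)cc2)cc1,"{<c1nc2cc(ccc2nc1)c3cc4nc(cnc4cc3)<, >c1ccc(cc1)c2ccc(cc2)c3c(cccc3)>}",{<c1ccc(cc1)c2ccc(cc2)c3ccc(cc3)c4cnc5ccc(cc5n4)c6ccc7ncc(nc7c6)>},table1,FALSE
Poly(ethylene adipate),,OCCOC( = O)CCCCC( = O),,"{<OCCO <, > C( = O)CCCCC( = O) >}",in-text,TRUE
Polyoxytrimethylene,,*CCCO*,,,in-text rotation,FALSE
Polyoxytrimethylene,,*CCOC*,,,in-text rotation,FALSE
Polyoxytrimethylene,,*COCC*,,,in-text rotation,FALSE
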