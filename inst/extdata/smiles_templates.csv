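template_id,family,template
benzene_13,benzenoid,c1cc({R1})cc({R2})c1
cinnamate_ester,cinnamic acid,O=C(OC)C=Cc1cc({R1})cc({R2})c1
cinnamamide,cinnamic acid,O=C(NC)C=Cc1cc({R1})cc({R2})c1
kavalactone_core,kavalactone,COC1=CC(=O)OC(C=Cc2cc({R1})cc({R2})c2)C1
dihydro_lactone,kavalactone,COC1=CC(=O)OC(CCc2cc({R1})cc({R2})c2)C1
piperamide,alkaloid,O=C(N1CCCC1)C=Cc1cc({R1})cc({R2})c1
indole_3,alkaloid,c1cc({R2})c2c(c1)c({R1})c[nH]2
pyridine_amide,alkaloid,O=C(NC({R2})C)c1cc({R1})ccn1
chalcone,chalcone,O=C(c1ccc({R1})cc1)C=Cc1ccc({R2})cc1
flavone,flavonoid,O=c1cc(-c2ccc({R1})cc2)oc2cc({R2})ccc12
menthane,terpene,CC1CCC(C(C)({R1})C({R2})O)CC1
glycoside,miscellaneous,OCC1OC(OC({R1})C)C(O{R2})C(O)C1O
phenethylamine,benzenoid,NCCc1cc({R1})cc({R2})c1
styrene_ketone,miscellaneous,CC(=O)C({R1})Cc1ccc({R2})cc1
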