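name,delta,note
mono-oxygenation,+1O,hydroxylation; oxygen incorporation
hydrogenation,+2H,reduction of a double bond
hydration,+2H+1O,water addition across a double bond
methoxylation,+1C+2H+1O,OCH3 for H
methylation,+1C+2H,net methyl transfer
oxidoreduction,-2H,dehydrogenation; double-bond formation
oxidation,+1O-2H,net alcohol-to-acid type change
malonylation,+3C+2H+3O,malonyl ester formation
hexosylation,+6C+10H+5O,hexose glycosylation (e.g. glucosylation)
dihydroxylation,+2H+2O,dihydroxylation of a double bond
coumaroylation,+9C+6H+2O,p-coumaroyl ester formation
pentosylation,+5C+8H+4O,pentose glycosylation (e.g. xylosylation)
dehydration,-2H-1O,water loss
demethylation,-1C-2H,methyl loss
demethoxylation,-1C-2H-1O,methoxy loss
dehydroxylation,-1O,hydroxyl loss
acetylation,+2C+2H+1O,acetyl ester/amide formation
deacetylation,-2C-2H-1O,acetyl loss
formylation,+1C+1O,formyl ester/amide formation
deformylation,-1C-1O,formyl loss
carboxylation,+1C+2O,carboxyl addition
decarboxylation,-1C-2O,CO2 loss
phosphorylation,+1H+3O+1P,phosphate ester formation
dephosphorylation,-1H-3O-1P,phosphate loss
sulfation,+3O+1S,sulfate ester formation
desulfation,-3O-1S,sulfate loss
glucuronidation,+6C+8H+6O,glucuronic acid conjugation
deglucuronidation,-6C-8H-6O,glucuronide loss
rhamnosylation,+6C+10H+4O,deoxyhexose glycosylation
derhamnosylation,-6C-10H-4O,deoxyhexose loss
dehexosylation,-6C-10H-5O,hexose loss
depentosylation,-5C-8H-4O,pentose loss
demalonylation,-3C-2H-3O,malonyl loss
decoumaroylation,-9C-6H-2O,coumaroyl loss
caffeoylation,+9C+6H+3O,caffeoyl ester formation
feruloylation,+10C+8H+3O,feruloyl ester formation
sinapoylation,+11C+10H+4O,sinapoyl ester formation
galloylation,+7C+4H+4O,galloyl ester formation
benzoylation,+7C+4H+1O,benzoyl ester formation
amination,+3H+1N,hydroamination
deamination,-3H-1N,amine loss
glycine-conjugation,+2C+3H+1N+1O,glycine amide conjugation
taurine-conjugation,+2C+5H+1N+2O+1S,taurine amide conjugation
glutathionylation,+10C+15H+3N+6O+1S,glutathione S-conjugation
cysteinylation,+3C+5H+1N+2O+1S,cysteine S-conjugation
ethylation,+2C+4H,net ethyl transfer
propylation,+3C+6H,net propyl transfer
prenylation,+5C+8H,prenyl (isoprenoid C5) transfer
geranylation,+10C+16H,geranyl (C10) transfer
farnesylation,+15C+24H,farnesyl (C15) transfer
malylation,+4C+4H+4O,malyl ester formation
succinylation,+4C+4H+3O,succinyl ester formation
quinylation,+7C+10H+5O,quinic acid ester formation
nitration,-1H+1N+2O,NO2 for H
sulfhydration,+1S,sulfur incorporation
pyruvylation,+3C+2H+2O,pyruvyl ester formation
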