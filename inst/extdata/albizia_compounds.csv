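name,source_id,logp,mol_weight,hbd,hba,druglike
Albigenin,Pubchem 101280261,6.02,426.67,1,2,Yes
Albigenic acid,Pubchem 101596822,5.42,472.7,3,4,Yes
Quebrachitol,ChEBI 111,-2.26,194.18,5,6,Yes
Phytosterol,Pubchem 12303662,7.19,414.17,1,1,Yes
Triterpenoids,Pubchem 71597391,3.94,472.66,4,5,Yes
Alpha Amyrin,Pubchem 225688,7.05,426.72,1,1,Yes
Beta Amyrin,Pubchem 225689,7.05,426.72,1,1,Yes
Epicatechin,Pubchem 182232,0.85,290.27,5,6,Yes
Umbellic acid,Pubchem 446611,0.89,180.16,3,4,Yes
Acacic acid,Pubchem 12305894,4.46,488.7,4,5,Yes
Benzoic acid,Pubchem 243,1.44,122.12,1,2,Yes
Benzyl alcohol,Pubchem 244,1.41,108.14,1,1,Yes
Celastrol,Pubchem 122724,5.16,450.61,2,4,Yes
Digitoxin,Pubchem 441207,2.61,764.94,5,13,No
L-arginine monocation,Pubchem 1549073,-3.14,175.21,4,2,Yes
Echinocystic acid,Pubchem 73309,5.3,472.7,3,4,Yes
Eupatin,Pubchem 5317287,2.12,360.31,3,8,Yes
Friedlein,Pubchem 244297,7.45,426.72,0,1,Yes
Kaempferol,Pubchem 5280863,1.58,286.24,4,6,Yes
Ascorbic acid,Pubchem 54670067,-1.28,176.12,4,6,Yes
Leucopelargonidin,Pubchem 3286789,0.58,290.27,5,6,Yes
Melacacidin,Pubchem 169996,0.36,306.27,6,7,Yes
Melanoxetin,Pubchem 15560442,1.19,302.24,5,7,Yes
Myricitrin,Pubchem 5281673,-0.23,464.38,8,12,Yes
Okanin,Pubchem 5281294,1.69,288.25,5,6,Yes
Oleanolic acid,Pubchem 10494,6.06,456.7,2,3,Yes
Quercetin,Pubchem 5280343,1.23,302.24,5,7,Yes
Reynoutrin,Pubchem 5320863,0,434.35,7,11,No
Vicenin 2,Pubchem 3084407,-2.07,594.52,11,15,No
Rutin,Pubchem 24832108,-1.12,610.52,10,16,No
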