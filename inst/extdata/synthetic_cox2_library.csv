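smiles,id
CC1(C)OC(c2ccc(S(N)(=O)=O)cc2)=C(c2cccc(F)c2)C1=O,polmacoxib
Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1,celecoxib
Cc1onc(-c2ccccc2)c1-c1ccc(S(N)(=O)=O)cc1,valdecoxib
O=C1OCC(c2ccc(S(C)(=O)=O)cc2)=C1c1ccccc1,rofecoxib
Cc1ccc(-c2ncc(Cl)cc2-c2ccc(S(C)(=O)=O)cc2)cn1,etoricoxib
CCC(=O)NS(=O)(=O)c1ccc(-c2c(-c3ccccc3)onc2C)cc1,parecoxib
Cc1ccc(Nc2c(F)cccc2Cl)c(CC(=O)O)c1,lumiracoxib
CC1(C)OC(=O)C(OCC2CC2)=C1c1ccc(S(C)(=O)=O)cc1,firocoxib
COc1ccc(-c2cc(C(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1F,deracoxib
Fc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1,mavacoxib
COc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1,sc560_analog
O=S(C)(=O)c1ccc(-c2cc(Br)sc2-c2ccc(F)cc2)cc1,dup697
Cc1cc(-c2ccc(S(C)(=O)=O)cc2)c(-c2ccc(F)cc2)o1,synthetic_furan_coxib
Cc1nc(-c2ccc(S(N)(=O)=O)cc2)c(-c2ccccc2)s1,synthetic_thiazole_coxib
O=C1OC(C)(C)C(=C1c1ccccc1)c1ccc(S(N)(=O)=O)cc1,synthetic_furanone_coxib
O=[N+]([O-])c1ccc(Oc2ccccc2)c(NS(C)(=O)=O)c1,nimesulide
OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl,diclofenac
COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1,indomethacin
CC(C(=O)O)c1ccc2cc(OC)ccc2c1,naproxen
CC(C)Cc1ccc(C(C)C(=O)O)cc1,ibuprofen
CC(=O)Oc1ccccc1C(=O)O,aspirin
CC(C(=O)O)c1cccc(C(=O)c2ccccc2)c1,ketoprofen
CC(C(=O)O)c1ccc(-c2ccccc2)c(F)c1,flurbiprofen
Cc1cccc(Nc2ccccc2C(=O)O)c1C,mefenamic_acid
Cn1cnc2c1c(=O)n(C)c(=O)n2C,caffeine
c1ccc2[nH]c(-c3ccccn3)nc2c1,benzimidazole_filler
COc1cccc2cc(C(=O)NCCN3CCCCC3)oc12,benzofuran_filler
O=C(Nc1ccc(Cl)cc1)c1ccccn1,anilide_filler
c1ccc(-c2nnc(SCc3ccccc3)o2)cc1,oxadiazole_filler
CCN(CC)CCNC(=O)c1ccc(N)cc1,procainamide
OCCN1CCN(CCCN2c3ccccc3Sc3ccc(Cl)cc32)CC1,perphenazine_like
CC(=O)Nc1ccc(O)cc1,acetaminophen
Clc1ccccc1-c1nc2ccccc2[nH]1,chlorobenzimidazole_filler
O=C(O)c1cc(O)c2ccccc2n1,quinoline_acid_filler
CN1CCC(=C2c3ccccc3CCc3ccccc32)CC1,amitriptyline_like
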