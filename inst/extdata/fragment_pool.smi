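# Curated fragment pool for the synthetic building-block generator.
# One family per base structure; id = 8-digit code, family = id %/% 1000.
Fc1ccccc1	00001001
Clc1ccccc1	00001002
Brc1ccccc1	00001003
Cc1ccccc1	00001004
COc1ccccc1	00001005
Nc1ccccc1	00001006
Cc1ccc(cc1)F	00002001
Cc1ccc(cc1)Cl	00002002
Cc1ccc(cc1)Br	00002003
Cc1ccc(cc1)C	00002004
COc1ccc(cc1)C	00002005
Cc1ccc(cc1)N	00002006
COc1ccc(cc1)F	00003001
COc1ccc(cc1)Cl	00003002
COc1ccc(cc1)Br	00003003
COc1ccc(cc1)OC	00003005
COc1ccc(cc1)N	00003006
Nc1ccc(cc1)F	00004001
Nc1ccc(cc1)Cl	00004002
Nc1ccc(cc1)Br	00004003
Nc1ccc(cc1)N	00004006
Oc1ccc(cc1)F	00005001
Oc1ccc(cc1)Cl	00005002
Oc1ccc(cc1)Br	00005003
Cc1ccc(cc1)O	00005004
COc1ccc(cc1)O	00005005
Nc1ccc(cc1)O	00005006
N#Cc1ccc(cc1)F	00006001
N#Cc1ccc(cc1)Cl	00006002
N#Cc1ccc(cc1)Br	00006003
N#Cc1ccc(cc1)C	00006004
COc1ccc(cc1)C#N	00006005
N#Cc1ccc(cc1)N	00006006
Fc1ccc(cc1)C(F)(F)F	00007001
FC(c1ccc(cc1)Cl)(F)F	00007002
FC(c1ccc(cc1)Br)(F)F	00007003
FC(c1ccc(cc1)C)(F)F	00007004
COc1ccc(cc1)C(F)(F)F	00007005
FC(c1ccc(cc1)N)(F)F	00007006
Fc1cccc(c1)Cl	00008001
Clc1cccc(c1)Cl	00008002
Clc1cccc(c1)Br	00008003
Cc1cccc(c1)Cl	00008004
COc1cccc(c1)Cl	00008005
Nc1cccc(c1)Cl	00008006
Fc1ccc(c(c1)F)F	00009001
Clc1ccc(c(c1)F)F	00009002
Brc1ccc(c(c1)F)F	00009003
Cc1ccc(c(c1)F)F	00009004
COc1ccc(c(c1)F)F	00009005
Nc1ccc(c(c1)F)F	00009006
CC(=O)c1ccc(cc1)F	00010001
CC(=O)c1ccc(cc1)Cl	00010002
CC(=O)c1ccc(cc1)Br	00010003
Cc1ccc(cc1)C(=O)C	00010004
COc1ccc(cc1)C(=O)C	00010005
CC(=O)c1ccc(cc1)N	00010006
OCc1ccc(cc1)F	00011001
OCc1ccc(cc1)Cl	00011002
OCc1ccc(cc1)Br	00011003
OCc1ccc(cc1)C	00011004
OCc1ccc(cc1)OC	00011005
OCc1ccc(cc1)N	00011006
Fc1ccccn1	00012001
Clc1ccccn1	00012002
Brc1ccccn1	00012003
Cc1ccccn1	00012004
COc1ccccn1	00012005
Nc1ccccn1	00012006
Fc1cccnc1	00013001
Clc1cccnc1	00013002
Brc1cccnc1	00013003
Cc1cccnc1	00013004
COc1cccnc1	00013005
Nc1cccnc1	00013006
Fc1ncccn1	00014001
Clc1ncccn1	00014002
Brc1ncccn1	00014003
Cc1ncccn1	00014004
COc1ncccn1	00014005
Nc1ncccn1	00014006
Cc1ccnc(c1)F	00015001
Cc1ccnc(c1)Cl	00015002
Cc1ccnc(c1)Br	00015003
Cc1ccnc(c1)C	00015004
COc1nccc(c1)C	00015005
Cc1ccnc(c1)N	00015006
Fc1cccs1	00016001
Clc1cccs1	00016002
Brc1cccs1	00016003
Cc1cccs1	00016004
COc1cccs1	00016005
Nc1cccs1	00016006
Cc1csc(c1)F	00017001
Cc1csc(c1)Cl	00017002
Cc1csc(c1)Br	00017003
Cc1scc(c1)C	00017004
COc1scc(c1)C	00017005
Cc1csc(c1)N	00017006
Fc1ccco1	00018001
Clc1ccco1	00018002
Brc1ccco1	00018003
Cc1ccco1	00018004
COc1ccco1	00018005
Nc1ccco1	00018006
Cc1coc(c1)F	00019001
Cc1coc(c1)Cl	00019002
Cc1coc(c1)Br	00019003
Cc1occ(c1)C	00019004
COc1occ(c1)C	00019005
Cc1coc(c1)N	00019006
Fc1cc[nH]n1	00020001
Clc1cc[nH]n1	00020002
Brc1cc[nH]n1	00020003
Cc1cc[nH]n1	00020004
COc1cc[nH]n1	00020005
Nc1cc[nH]n1	00020006
Cn1ccc(c1)F	00021001
Cn1ccc(c1)Cl	00021002
Cn1ccc(c1)Br	00021003
Cc1ccn(c1)C	00021004
COc1ccn(c1)C	00021005
Cn1ccc(c1)N	00021006
Fc1cscn1	00022001
Clc1cscn1	00022002
Brc1cscn1	00022003
Cc1cscn1	00022004
COc1cscn1	00022005
Nc1cscn1	00022006
Fc1cocn1	00023001
Clc1cocn1	00023002
Brc1cocn1	00023003
Cc1cocn1	00023004
COc1cocn1	00023005
Nc1cocn1	00023006
Cn1cc(nc1)F	00024001
Cn1cc(nc1)Cl	00024002
Cn1cc(nc1)Br	00024003
Cn1cnc(c1)C	00024004
COc1ncn(c1)C	00024005
Cn1cc(nc1)N	00024006
Fc1cc2c(o1)cccc2	00025001
Clc1cc2c(o1)cccc2	00025002
Brc1cc2c(o1)cccc2	00025003
Cc1cc2c(o1)cccc2	00025004
COc1cc2c(o1)cccc2	00025005
Nc1cc2c(o1)cccc2	00025006
Fc1cc2c(s1)cccc2	00026001
Clc1cc2c(s1)cccc2	00026002
Brc1cc2c(s1)cccc2	00026003
Cc1cc2c(s1)cccc2	00026004
COc1cc2c(s1)cccc2	00026005
Nc1cc2c(s1)cccc2	00026006
Fc1cc2c([nH]1)cccc2	00027001
Clc1cc2c([nH]1)cccc2	00027002
Brc1cc2c([nH]1)cccc2	00027003
Cc1cc2c([nH]1)cccc2	00027004
COc1cc2c([nH]1)cccc2	00027005
Nc1cc2c([nH]1)cccc2	00027006
Fc1cnc2c(n1)cccc2	00028001
Clc1cnc2c(n1)cccc2	00028002
Brc1cnc2c(n1)cccc2	00028003
Cc1cnc2c(n1)cccc2	00028004
COc1cnc2c(n1)cccc2	00028005
Nc1cnc2c(n1)cccc2	00028006
CCCC(F)C	00029001
CCCC(Cl)C	00029002
CCCC(Br)C	00029003
CCCC(C)C	00029004
CCCC(OC)C	00029005
CCCC(N)C	00029006
CCCCCF	00030001
CCCCCCl	00030002
CCCCCBr	00030003
CCCCCC	00030004
CCCCCOC	00030005
CCCCCN	00030006
FC1CCCCC1	00031001
ClC1CCCCC1	00031002
BrC1CCCCC1	00031003
CC1CCCCC1	00031004
COC1CCCCC1	00031005
NC1CCCCC1	00031006
FC1CCCC1	00032001
ClC1CCCC1	00032002
BrC1CCCC1	00032003
CC1CCCC1	00032004
COC1CCCC1	00032005
NC1CCCC1	00032006
CC(CC(F)C)C	00033001
CC(CC(Cl)C)C	00033002
CC(CC(Br)C)C	00033003
CC(CC(C)C)C	00033004
COC(CC(C)C)C	00033005
CC(CC(N)C)C	00033006
FCN1CCCC1	00034001
ClCN1CCCC1	00034002
BrCN1CCCC1	00034003
CCN1CCCC1	00034004
COCN1CCCC1	00034005
NCN1CCCC1	00034006
FCC1CCCO1	00035001
ClCC1CCCO1	00035002
BrCC1CCCO1	00035003
CCC1CCCO1	00035004
COCC1CCCO1	00035005
NCC1CCCO1	00035006
CSCCCF	00036001
CSCCCCl	00036002
CSCCCBr	00036003
CCCCSC	00036004
COCCCSC	00036005
CSCCCN	00036006
NCCCCF	00037001
NCCCCCl	00037002
NCCCCBr	00037003
COCCCCN	00037005
NCCCCN	00037006
OCCCCF	00038001
OCCCCCl	00038002
OCCCCBr	00038003
CCCCCO	00038004
COCCCCO	00038005
NCCCCO	00038006
CC(C(N)C)F	00039001
CC(C(N)C)Cl	00039002
CC(C(N)C)Br	00039003
CC(C(C)C)N	00039004
COC(C(N)C)C	00039005
CC(C(N)C)N	00039006
FCCC1CC1	00040001
ClCCC1CC1	00040002
BrCCC1CC1	00040003
CCCC1CC1	00040004
COCCC1CC1	00040005
NCCC1CC1	00040006
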