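id,name,group,risk_group,detection_limit,carcinogen_flag
PCB28,PCB 28,PCB,OC,0.06,TRUE
PCB52,PCB 52,PCB,OC,0.05,TRUE
PCB101,PCB 101,PCB,OC,0.03,TRUE
PCB118,PCB 118,PCB,OC,0.02,TRUE
PCB153,PCB 153,PCB,OC,0.08,TRUE
PCB138,PCB 138,PCB,OC,0.06,TRUE
PCB180,PCB 180,PCB,OC,0.05,TRUE
PeCB,Pentachlorobenzene,OCP,OC,0.01,FALSE
HCB,Hexachlorobenzene,OCP,OC,0.13,TRUE
aHCH,alpha-Hexachlorocyclohexane,OCP,OC,0.12,TRUE
bHCH,beta-Hexachlorocyclohexane,OCP,OC,0.03,TRUE
gHCH,gamma-Hexachlorocyclohexane,OCP,OC,0.1,TRUE
opDDE,"o,p'-DDE",OCP,DDX,0.01,TRUE
ppDDE,"p,p'-DDE",OCP,DDX,0.34,TRUE
opDDD,"o,p'-DDD",OCP,DDX,0.01,TRUE
ppDDD,"p,p'-DDD",OCP,DDX,0.04,TRUE
opDDT,"o,p'-DDT",OCP,DDX,0.05,TRUE
ppDDT,"p,p'-DDT",OCP,DDX,0.12,TRUE
N,Naphthalene,PAH,PAH,4.38,FALSE
Ace,Acenaphthene,PAH,PAH,0.06,FALSE
Fluor,Fluorene,PAH,PAH,0.92,FALSE
Ant,Anthracene,PAH,PAH,0.67,FALSE
Fl,Fluoranthene,PAH,PAH,10.58,FALSE
Pyr,Pyrene,PAH,PAH,8.31,FALSE
BaA,Benz(a)anthracene,PAH,PAH,3,TRUE
Chr,Chrysene,PAH,PAH,4.58,TRUE
BbF,Benzo(b)fluoranthene,PAH,PAH,5.58,TRUE
BkF,Benzo(k)fluoranthene,PAH,PAH,2.08,TRUE
BaP,Benzo(a)pyrene,PAH,PAH,3.62,TRUE
Ipyr,"Indeno(1,2,3-cd)pyrene",PAH,PAH,2.77,TRUE
DBahAnt,Dibenz(ah)anthracene,PAH,PAH,0.1,TRUE
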