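id,rfd_o,rfd_i,csf_o,csf_i,abs_skin,vf_s,pef,volatile
PCB28,7.228821806775755e-6,7.228821806775755e-6,0.6788516388214836,0.6788516388214836,0.14,NA,1316000000,FALSE
PCB52,7.228821806775755e-6,7.228821806775755e-6,0.6788516388214836,0.6788516388214836,0.14,NA,1316000000,FALSE
PCB101,6.7124773920060595e-6,6.7124773920060595e-6,0.7310709956539053,0.7310709956539053,0.14,NA,1316000000,FALSE
PCB118,7.228821806775755e-6,7.228821806775755e-6,0.6788516388214836,0.6788516388214836,0.14,NA,1316000000,FALSE
PCB153,7.274286094868685e-6,7.274286094868685e-6,0.6746088160788491,0.6746088160788491,0.14,NA,1316000000,FALSE
PCB138,7.228821806775755e-6,7.228821806775755e-6,0.6788516388214836,0.6788516388214836,0.14,NA,1316000000,FALSE
PCB180,7.2288218067757575e-6,7.2288218067757575e-6,0.6788516388214835,0.6788516388214835,0.14,NA,1316000000,FALSE
PeCB,0.004336272979823649,0.004336272979823649,NA,NA,0.1,NA,1316000000,FALSE
HCB,9.284236503558758e-6,9.284236503558758e-6,0.5231284063664804,0.5231284063664804,0.1,NA,1316000000,FALSE
aHCH,2.393642135484375e-6,2.393642135484375e-6,2.029061811051956,2.029061811051956,0.1,NA,1316000000,FALSE
bHCH,8.41127940386252e-6,8.41127940386252e-6,0.5774208195017156,0.5774208195017156,0.1,NA,1316000000,FALSE
gHCH,1.617068465392569e-5,1.617068465392569e-5,0.3003489308201382,0.3003489308201382,0.1,NA,1316000000,FALSE
opDDE,4.400186300387943e-5,4.400186300387943e-5,0.11037823207640078,0.11037823207640078,0.1,NA,1316000000,FALSE
ppDDE,4.519574295289577e-5,4.519574295289577e-5,0.10746250706616631,0.10746250706616631,0.1,NA,1316000000,FALSE
opDDD,6.228708162993601e-5,6.228708162993601e-5,0.07797520319368971,0.07797520319368971,0.1,NA,1316000000,FALSE
ppDDD,6.205724000030524e-5,6.205724000030524e-5,0.07826400024255521,0.07826400024255521,0.1,NA,1316000000,FALSE
opDDT,5.680025433995404e-5,5.680025433995404e-5,0.08550750173348834,0.08550750173348834,0.1,NA,1316000000,FALSE
ppDDT,5.615458849395696e-5,5.615458849395696e-5,0.08649066757846269,0.08649066757846269,0.1,NA,1316000000,FALSE
N,1.1922202301780717e-4,1.1922202301780717e-4,NA,NA,0.13,NA,1316000000,FALSE
Ace,0.31513682708290136,0.31513682708290136,NA,NA,0.13,NA,1316000000,FALSE
Fluor,0.2101319267907802,0.2101319267907802,NA,NA,0.13,NA,1316000000,FALSE
Ant,1.6860849547227277,1.6860849547227277,NA,NA,0.13,NA,1316000000,FALSE
Fl,0.21309320044629404,0.21309320044629404,NA,NA,0.13,NA,1316000000,FALSE
Pyr,0.1627950479539301,0.1627950479539301,NA,NA,0.13,NA,1316000000,FALSE
BaA,2.0584778781379196e-5,2.0584778781379196e-5,0.2378269279415287,0.2378269279415287,0.13,NA,1316000000,FALSE
Chr,0.0020407731115565297,0.0020407731115565297,0.0023989020005253875,0.0023989020005253875,0.13,NA,1316000000,FALSE
BbF,2.0354940097188692e-5,2.0354940097188692e-5,0.24051236095789505,0.24051236095789505,0.13,NA,1316000000,FALSE
BkF,2.0485061251506896e-4,2.0485061251506896e-4,0.023898462590983244,0.023898462590983244,0.13,NA,1316000000,FALSE
BaP,2.0485782880704666e-6,2.0485782880704666e-6,2.389762074722809,2.389762074722809,0.13,NA,1316000000,FALSE
Ipyr,2.062675415115077e-5,2.062675415115077e-5,0.23734295100706626,0.23734295100706626,0.13,NA,1316000000,FALSE
DBahAnt,2.0714977242473143e-6,2.0714977242473143e-6,2.363321302566343,2.363321302566343,0.13,NA,1316000000,FALSE
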