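site_id,PCB28,PCB52,PCB101,PCB118,PCB153,PCB138,PCB180,PeCB,HCB,aHCH,bHCH,gHCH,opDDE,ppDDE,opDDD,ppDDD,opDDT,ppDDT,N,Ace,Fluor,Ant,Fl,Pyr,BaA,Chr,BbF,BkF,BaP,Ipyr,DBahAnt
site_001,  2.668,  3.711,4.49786,3.70909,8.34606,8.13569,11.7931,5.46454,  42.82,21.5178,1.60684,13.6593,0.0388808,0.82033,0.0637651,0.19016,0.305026,1.19412,<DL,0.519148,1.24241,2.07631,22.4169,32.1487,10.7411,18.4007,20.2724,9.87791,  15.06,9.61622,2.54175
site_002,1.69018,5.87223,4.51181,3.47765,5.38885,13.0196, 5.0122,2.87473,31.5589,11.4821,2.12964,8.05265,0.0182603,1.16993,0.0489585,0.0898627,0.106327,1.17135,<DL,0.744792,0.935251,1.50691,28.1833,12.0476, 11.971,21.3878,7.68669,6.85459,29.1713,7.05943,0.718856
site_003,<DL,0.0702018,0.226682,0.147811,0.38151,0.259102,0.208313,0.143116,1.25793,0.353672,0.108343,0.397725,0.187851,4.25381,0.226711,0.241041,0.600328,3.71817,7.73971,1.64462,2.84849,4.21367, 85.706, 64.377,28.5037,64.5538,61.4488,25.9066,53.6809,36.0882,2.86211
site_004,<DL,<DL,<DL,<DL,<DL,0.10867,0.0850622,0.0348918,0.363389,<DL,<DL,0.14384,0.0299004,1.57918,0.0564754,0.222056,0.154619,1.32372,4.93177,0.453547,<DL, 1.9879,25.9968,15.2704, 12.487,13.6428,19.8652,5.31273, 17.685,8.68466,0.480198
site_005,11.4363,10.8112,11.0986,9.98543,35.8222,51.5485,23.0358,20.3155,260.173,32.4748,17.6426,32.0035,0.164145,3.18842,0.170873,0.305057,0.449374,7.01939,7.75326,1.29489,1.87744,7.24761,186.462,73.5861,18.1158,57.0645, 59.761,19.9598,52.7814,29.6532,3.19058
site_006,0.123503,0.156144,0.164453,0.0622581,0.311867,0.256843,0.24525,0.172903,1.40846,0.639797,0.0630798,0.177026,0.115932,3.08629,0.103844,0.230153,0.30765,3.18399,12.7313, 1.2532,3.47197,5.21965,71.5739,52.1192,28.3493,34.6026, 26.132,13.5864,25.1953,24.3924,2.64952
site_007,1.76153,2.15597,3.57701,1.08615,5.46886,9.18789,8.51537,2.37587,48.8274,8.32415,3.34995,19.1115,0.0358033,1.69358,0.0436545,0.126283,0.130869,0.799477,<DL,0.347999,0.992711,1.56179, 13.524,  10.86,11.8102,12.4609,18.2854,4.00991,13.6734,10.2314,0.546915
site_008,0.100777,0.14467,0.11679,0.106872,0.220673,0.282496,0.294736,0.171705,0.813742,0.620751,0.180612,0.257012,22.4449, 571.35, 34.169,92.3977,45.5436,849.019,7.11133,0.986769, 1.8904,5.80361,78.1524,49.5139,17.1998,74.8812,34.8685,9.12464,49.3414,21.3525,2.11145
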