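area,zone,kp_range,direction,Qf_m3_day,bank_length_m,Qu_printed,row_type
A1,Z1,116-114.5,loss,-668,1547,-432,zone
A1,S1,114.5-112,loss,-52,531,-98,zone
A1,Z2,114.5-112,gain,393,3545,111,zone
A2,Z3,113-111,loss,-1890,2040,-927,zone
A2,Z4,111-109,gain,6097,2809,2170,zone
A3,Z5,111-110.5,loss,-354,587,-603,zone
A3,S2,110.5-110,gain,57,664,NA,zone
A3,Z6,110-106,loss,-77,431,-178,zone
A3,Z6,110-106,gain,1723,3709,465,zone
A3,Z7,106-102.5,loss,-462,3057,-151,zone
A3,Z7,106-102.5,gain,83,492,NA,zone
A3,Z8,102.5-99,loss,-35,21,-1693,zone
A3,Z8,102.5-99,gain,54340,4190,12968,zone
ALL,total,116-99,loss,-3538,8214,-431,total
ALL,total,116-99,gain,62566,14678,4263,total
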