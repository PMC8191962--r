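rank,oob,cwf
1,Iavc_2ch_BI,Iavc_2ch_BI
2,Iavc_2ch_std,P_3ch_AAs
3,E_4ch_BS,E_2ch_AA
4,Tpeak_3ch_AAs,Tpeak_4ch_mean
5,Ipeak_4ch_std,E_4ch_MS
6,Tpeak_4ch_MS,E_4ch_BS
7,Tpeak_2ch_MI,E_2ch_mean
8,Ipeak_4ch_AS,P_4ch_AS
9,E_3ch_AAs,Tpeak_2ch_MI
10,P_3ch_MAs,Ipeak_2ch_AA
11,E_4ch_AS,Iavc_4ch_L
12,Ipeak_4ch_BL,Iavc_4ch_AS
13,E_4ch_MS,Ipeak_4ch_L
14,E_4ch_L,E_2ch_BI
15,Tpeak_4ch_mean,Tpeak_3ch_AAs
16,Ipeak_4ch_L,E_2ch_I
17,Iavc_4ch_BL,E_2ch_MA
18,Tpeak_4ch_BS,P_3ch_MAs
19,E_2ch_mean,Tpeak_4ch_MS
20,Tavc_2ch,E_2ch_MI
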