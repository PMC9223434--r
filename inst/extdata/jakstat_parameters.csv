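index,name,description,ranked
1,kv,cytoplasmic/nuclear volume ratio,TRUE
2,vi1t,IRF1 transcription rate,TRUE
3,vs1t,STAT1 transcription rate,TRUE
4,vl2t,LMP2 transcription rate,TRUE
5,vt1t,TAP1 transcription rate,TRUE
6,ktransl,translation rate,TRUE
7,T,time constant for inertial elements,TRUE
8,ks1deg,STAT1 degradation rate,TRUE
9,ks1pdeg,STAT1p degradation rate,TRUE
10,ks2deg,STAT2 degradation rate,TRUE
11,ks2pdeg,STAT2p degradation rate,TRUE
12,ki1deg,IRF1active degradation rate,TRUE
13,ki1_indeg,IRF1inactive degradation rate,TRUE
14,ks1t_deg,STAT1 transcript degradation rate,TRUE
15,ks2t_deg,STAT2 transcript degradation rate,TRUE
16,ki1t_deg,IRF1 transcript degradation rate,TRUE
17,kl2t_deg,LMP2 transcript degradation rate,TRUE
18,kt1t_deg,TAP1 transcript degradation rate,TRUE
19,kinv_s1s1,cyt. [STAT1p|STAT1p] dissociation rate,TRUE
20,kinv_s1s1_n,nuc. [STAT1p|STAT1p] dissociation rate,TRUE
21,kinv_s1s2,cyt. [STAT1p|STAT2p] dissociation rate,TRUE
22,kinv_s1s2_n,nuc. [STAT1p|STAT2p] dissociation rate,TRUE
23,kinv_phys1s1,nuc. [STAT1p|STAT1p|PHY] dissociation rate,TRUE
24,kinv_s1i1,nuc. [STAT1|IRF1active] dissociation rate,TRUE
25,ks1i1deg,[STAT1|IRF1] degradation rate,TRUE
26,ks1s1,[STAT1p|STAT1p] complex creation rate,TRUE
27,ks1s2,[STAT1p|STAT2p] complex creation rate,TRUE
28,kphys1s1,[PHY|STAT1p|STAT1p] complex creation rate,TRUE
29,ks1i1,nuc. [IRF1|STAT1] complex creation rate,TRUE
30,kactivation,PHY activation,TRUE
31,kinacti1,IRF1 inactivation rate,TRUE
32,ks1tprod,STAT1 constitutive mRNA production rate,TRUE
33,ks2tprod,STAT2 constitutive mRNA production rate,TRUE
34,kl2tprod,LMP2 constitutive mRNA production rate,TRUE
35,kt1tprod,TAP1 constitutive mRNA production rate,TRUE
36,es1,STAT1 nuclear export,TRUE
37,is1,STAT1 nuclear import,TRUE
38,es2,STAT2 nuclear export,TRUE
39,is2,STAT2 nuclear import,TRUE
40,is1s1,[STAT1p|STAT1p] nuclear import,TRUE
41,is1s2,[STAT1p|STAT2p] nuclear import,TRUE
42,ii1,IRF1active nuclear import,TRUE
43,ei1,IRF1active nuclear export,TRUE
44,ei1_in,IRF1inactive nuclear export,TRUE
45,ks1_phos,STAT1 phosphorylation rate,TRUE
46,ks1_dephc,STAT1p dephosphorylation rate,TRUE
47,ks2_phos,STAT2 phosphorylation rate,TRUE
48,ks2_dephc,STAT2p dephosphorylation rate,TRUE
49,ks1_phos_sat,STAT1 phosphorylation saturation constant (excluded from sensitivity analysis),FALSE
50,ks2_phos_sat,STAT2 phosphorylation saturation constant (excluded from sensitivity analysis),FALSE
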