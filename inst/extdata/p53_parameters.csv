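index,name,description,ranked
1,a6,Max DNA damage rate,TRUE
2,q3,Coefficient governing apoptotic factor synthesis,TRUE
3,d9,Apoptotic factors degradation rate,TRUE
4,p1,Max synthesis rate of apoptotic factor,TRUE
5,a0,Spontaneous p53n phosphorylation rate,TRUE
6,a1,DSB-induced p53n phosphorylation rate,TRUE
7,a2,PIP activation rate,TRUE
8,a3,AKT activation rate,TRUE
9,a4,Mdm2 phosphorylation rate,TRUE
10,c0,PIPp dephosphorylation rate (by PTEN),TRUE
11,c1,AKTp inactivation rate,TRUE
12,c2,Mdm2p dephosphorylation rate,TRUE
13,c3,Spontaneous p53pn dephosphorylation rate,TRUE
14,p0,p53n production rate,TRUE
15,s0,Mdm2 transcription rate,TRUE
16,s1,PTEN transcription rate,TRUE
17,t0,Mdm2 translation rate,TRUE
18,t1,PTEN translation rate,TRUE
19,d0,Mdm2 spontaneous deg. rate (all Mdm2 forms),TRUE
20,d1,DSB-induced Mdm2 deg. rate (all Mdm2 forms),TRUE
21,d2,PTEN degradation rate,TRUE
22,d3,Spontaneous p53n degradation rate,TRUE
23,d4,Mdm2pn-induced p53n degradation rate,TRUE
24,d5,Spontaneous p53pn degradation rate,TRUE
25,d6,Mdm2pn-induced p53pn degradation rate,TRUE
26,d7,Mdm2t degradation rate,TRUE
27,d8,PTENt degradation rate,TRUE
28,i0,Mdm2p nuclear import,TRUE
29,e0,Mdm2pn nuclear export,TRUE
30,AKTtot,Total number of Akt molecules (AKT+AKTp),TRUE
31,PIPtot,Total number of PIP molecules (PIP+PIPp),TRUE
32,drep,DNA repair rate,TRUE
33,q0,Spontaneous activation of Mdm2 and PTEN genes,TRUE
34,q1,p53pn-depended activation of Mdm2 and PTEN genes,TRUE
35,q2,Mdm2 and PTEN genes inactivation rate,TRUE
36,h0,Structural constant (excluded from sensitivity analysis),FALSE
37,NSAT,Saturation constant (excluded from sensitivity analysis),FALSE
38,dDAM,Structural constant (excluded from sensitivity analysis),FALSE
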