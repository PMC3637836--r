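Region,Name,Urban,Class,e1,e2,e3,e4,e5,e6,e7
1,Duesseldorf,1,3,0,0,0.98,0.02,0,0,0
2,Duisburg,1,2,0,1,0,0,0,0,0
3,Essen,1,3,0,0.05,0.95,0,0,0,0
4,Krefeld,1,4,0,0,0.01,0.99,0,0,0
5,Moenchengladbach,1,2,0,1,0,0,0,0,0
6,Muelheim a.d. Ruhr,1,4,0,0,0,1,0,0,0
7,Oberhausen,1,2,0,1,0,0,0,0,0
8,Remscheid,1,3,0,0,1,0,0,0,0
9,Solingen,1,4,0,0,0,0.96,0.04,0,0
10,Wuppertal,1,4,0,0,0.12,0.88,0,0,0
11,Kleve,0,3,0,0,1,0,0,0,0
12,Mettmann,0,5,0,0,0,0,1,0,0
13,Neuss,0,5,0,0,0,0,1,0,0
14,Viersen,0,3,0,0,0.98,0.02,0,0,0
15,Wesel,0,4,0,0,0.13,0.87,0,0,0
16,Aachen (city),1,5,0,0,0,0,1,0,0
17,Bonn,1,7,0,0,0,0,0,0,1
18,Koeln,1,3,0,0,0.88,0.12,0,0,0
19,Leverkusen,1,5,0,0,0,0,1,0,0
20,Aachen (rural),0,3,0,0,1,0,0,0,0
21,Dueren,0,3,0,0,0.97,0.03,0,0,0
22,Erftkreis,0,3,0,0,0.83,0.17,0,0,0
23,Euskirchen,0,3,0,0,1,0,0,0,0
24,Heinsberg,0,3,0,0,0.79,0.21,0,0,0
25,Oberbergischer Kreis,0,4,0,0,0,1,0,0,0
26,Rheinisch-Bergischer Kreis,0,6,0,0,0,0,0,1,0
27,Rhein-Sieg-Kreis,0,5,0,0,0,0,0.74,0.26,0
28,Bottrop,1,3,0,0.01,0.99,0,0,0,0
29,Gelsenkirchen,1,1,1,0,0,0,0,0,0
30,Muenster,1,7,0,0,0,0,0,0,1
31,Borken,0,5,0,0,0,0,0.98,0.02,0
32,Coesfeld,0,6,0,0,0,0,0,1,0
33,Recklinghausen,0,2,0,0.94,0.06,0,0,0,0
34,Steinfurt,0,6,0,0,0,0,0,1,0
35,Warendorf,0,6,0,0,0,0,0.44,0.56,0
36,Bielefeld,1,6,0,0,0,0,0,1,0
37,Guetersloh,0,6,0,0,0,0,0,1,0
38,Herford,0,6,0,0,0,0,0,1,0
39,Hoexter,0,6,0,0,0,0,0.09,0.91,0
40,Lippe,0,6,0,0,0,0,0,1,0
41,Minden-Luebbecke,0,6,0,0,0,0,0.01,0.99,0
42,Paderborn,0,6,0,0,0,0,0.02,0.98,0
43,Bochum,1,3,0,0,1,0,0,0,0
44,Dortmund,1,2,0,1,0,0,0,0,0
45,Hagen,1,4,0,0,0,1,0,0,0
46,Hamm,1,4,0,0,0.27,0.73,0,0,0
47,Herne,1,2,0,1,0,0,0,0,0
48,Ennepe-Ruhr-Kreis,0,4,0,0,0,1,0,0,0
49,Hochsauerlandkreis,0,5,0,0,0,0,1,0,0
50,Maerkischer Kreis,0,3,0,0,1,0,0,0,0
51,Olpe,0,5,0,0,0,0,0.84,0.16,0
52,Siegen-Wittgenstein,0,5,0,0,0,0.06,0.94,0,0
53,Soest,0,4,0,0,0.32,0.68,0,0,0
54,Unna,0,4,0,0,0.07,0.93,0,0,0
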