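no,name,formula,class,origin,standard_confirmed,rt_min,provenance
1,RAM,C6H12O5,Saccharide,HQ,FALSE,1.63,
2,XLS,C5H10O5,Saccharide,HQ,FALSE,1.64,
3,"7,2'-Dihydroxy-3',4'-dimethoxyisoflavone-7-O-beta-D-glucoside",C23H24O11,Flavonoids,HQ,FALSE,1.66,
4,Inositol,C6H12O6,Others,YYH,FALSE,1.67,
5,"3,4,5-Trimethoxytoluene",C10H14O3,Others,YYH,FALSE,1.68,
6,Maohuoside A,C27H32O12,Flavonoids,YYH,FALSE,1.69,
7,Wanepimedoside_qt,C21H22O7,Flavonoids,YYH,FALSE,1.76,
8,Chlorogenic acid,C16H18O9,Phenylpropanoids (phenylpropionic acid),YYH,FALSE,5.25,
9,Icariside B1,C19H30O8,Terpenoids (monocyclic monoterpenoids),YYH,FALSE,6.44,
10,Icariside D1,C19H28O10,Terpenoids (monocyclic monoterpenoids),YYH,FALSE,6.49,
11,Icariside E1,C26H36O12,Phenylpropanoids (phenylpropanols),YYH,FALSE,6.87,
12,Isomyricitrin,C21H20O13,Flavonoids,YYH,FALSE,6.92,
13,Ikarisoside B,C32H38O15,Flavonoids,YYH,FALSE,7.22,
14,Calycosin-7-glucoside,C22H22O10,Flavonoids,HQ,TRUE,7.86,
15,Hyperoside,C21H20O12,Flavonoids,YYH;NX,FALSE,7.92,
16,Robinetin,C15H10O7,Flavonoids,YYH,FALSE,8.00,
17,Caohuoside D,C28H34O12,Flavonoids,YYH,FALSE,8.17,
18,Ecdysterone,C27H44O7,Steroids,NX,TRUE,8.39,
19,Eugenol rutinoside,C22H32O11,Phenylpropanoids (Styrene),YYH,FALSE,8.42,
20,"Isomucronulatol-7,2'-di-O-glucosiole",C29H38O15,Flavonoids,HQ,FALSE,10.13,
21,Wogonin,C16H12O5,Flavonoids,NX,FALSE,11.14,
22,Hexandraside E,C32H38O16,Flavonoids,YYH,FALSE,12.07,
23,"1-O-{(3beta,5xi,9xi)-3-[(6-Methyl-beta-D-glucopyranuronosyl)oxy]-28-oxoolean-12-en-28-yl}-beta-D-glucopyranose",C43H68O14,Triterpenoids,NX,FALSE,12.18,
24,Sitosterol,C29H50O,Steroids,YYH;NX,FALSE,12.41,
25,Diphylloside A,C38H48O20,Flavonoids,YYH,FALSE,12.81,
26,Epimedoside D,C37H46O19,Flavonoids,YYH,FALSE,13.06,
27,Epimedoside,C37H44O17,Flavonoids,YYH,FALSE,13.29,
28,Diphylloside B,C38H48O19,Flavonoids,YYH,FALSE,13.32,
29,Epimedoside A,C32H38O15,Flavonoids,YYH,FALSE,13.39,
30,"(2S,3S)-3,5-dihydroxy-2-(4-hydroxyphenyl)-8-(3-methyl-2-buten-1-yl)-4-oxo-3,4-dihydro-2H-chromen-7-yl beta-D-glucopyranoside",C26H30O11,Flavonoids,YYH,FALSE,13.41,
31,Ononin,C22H22O9,Flavonoids,HQ,TRUE,14.13,
32,3-Hexenyl-beta-glucopyranoside,C12H22O6,Saccharide,YYH,FALSE,15.81,
33,Calycosin,C16H12O5,Flavonoids,HQ,TRUE,16.05,
34,Epimedin A,C39H50O20,Flavonoids,YYH,TRUE,17.76,printed formula C39H50O19 duplicates epimedin C; printed m/z (883.2882 formate and 839.2961 protonated) and the serum/metabolite tables require C39H50O20
35,Epimedin B,C38H48O19,Flavonoids,YYH,TRUE,18.46,printed formula C38H48O18; printed m/z (853.2774 formate and 809.2855 protonated) and the metabolite table require C38H48O19
36,Icaritin,C21H20O6,Flavonoids,YYH,FALSE,18.88,
37,Epimedin C,C39H50O19,Flavonoids,YYH,TRUE,18.93,
38,"3,5,7-Trihydroxy-8-(3-methoxy-3-methylbutyl)-2-(4-methoxyphenyl)-4H-chromen-4-one",C22H24O7,Flavonoids,YYH,FALSE,18.99,
39,Hexandraside B,C41H52O21,Flavonoids,YYH,FALSE,19.17,
40,Icariside I,C27H30O11,Flavonoids,YYH,FALSE,19.21,
41,Icariin,C33H40O15,Flavonoids,YYH,TRUE,19.22,
42,Lariciresinol,C20H24O6,Phenylpropanoids (lignans),HQ,FALSE,19.23,
43,"8-Hydroxy-6-methyl-9,10-dioxo-9,10-dihydro-1-anthracenyl 6-O-(3,4,5-trihydroxybenzoyl)-beta-D-glucopyranoside",C28H24O13,Anthraquinones,NX,FALSE,19.26,
44,Rubschisantherin,C25H30O8,Phenylpropanoids (lignans),NX,FALSE,19.63,
45,Korepimedoside A,C36H42O17,Flavonoids,YYH,FALSE,20.82,
46,Korepimedoside C,C41H52O21,Flavonoids,YYH,FALSE,20.94,
47,Achyranthoside D trimethyl ester,C56H88O25,Triterpenoids,NX,FALSE,21.01,
48,Chikusetsusaponin V butyl ester,C52H84O19,Triterpenoids,NX,FALSE,21.08,
49,Achyranthoside D,C53H82O25,Triterpenoids,NX,FALSE,21.09,
50,Chikusetsusaponin IV,C47H74O18,Triterpenoids,NX,FALSE,21.11,
51,Ginsenoside Ro,C48H76O19,Triterpenoids,NX,TRUE,21.19,
52,Ikarisoside F,C31H36O14,Flavonoids,YYH,FALSE,21.24,
53,Acuminatoside,C45H60O24,Flavonoids,YYH,FALSE,21.28,
54,Wushanicariin,C27H30O11,Flavonoids,YYH,FALSE,21.31,
55,Sagittatoside C,C35H42O16,Flavonoids,YYH,FALSE,21.56,
56,Taibaienoside IV,C46H74O14,Triterpenoids,NX,FALSE,21.61,
57,8-Prenylkaempferol,C20H18O6,Flavonoids,YYH,FALSE,21.78,
58,Formononetin,C16H12O4,Flavonoids,HQ,FALSE,21.79,
59,"(6aR,11aR)-9,10-dimethoxy-6a,11a-dihydro-6H-benzofurano[3,2-c]chromen-3-ol",C17H16O5,Flavonoids,HQ,FALSE,22.23,
60,Achyranthoside C,C47H72O20,Triterpenoids,NX,FALSE,22.33,
61,Sagittatoside B,C32H38O14,Flavonoids,YYH,FALSE,23.03,
62,"1,2-Bis(4-hydroxy-3-methoxyphenyl)-1,3-propanediol",C17H20O6,Phenylpropanoids (phenylpropionic acid),YYH,FALSE,23.54,
63,Icariside II,C27H30O10,Flavonoids,YYH,FALSE,23.89,
64,Anhydroicaritin,C21H20O6,Flavonoids,YYH,FALSE,23.90,
65,Zingibroside R1,C42H66O14,Triterpenoids,NX,FALSE,24.53,
66,Icariside B3,C19H30O9,Terpenoids (Monocyclic monoterpenoids),YYH,FALSE,24.58,
67,Acetylastragaloside I_qt,C41H64O12,Triterpenoids,HQ,FALSE,25.14,
68,Yinyanghuo D,C20H18O5,Flavonoids,YYH,FALSE,25.55,
69,Yinyanghuo B,C25H26O6,Flavonoids,YYH,FALSE,25.84,
70,"13-Hydroxy-9,11-octadecadienoic acid",C18H32O3,Organic acids,HQ,FALSE,26.15,
71,Achyranthoside C_qt,C41H62O15,Triterpenoids,NX,FALSE,26.23,
72,Korepimedoside B,C45H56O23,Flavonoids,YYH,FALSE,26.71,
73,Inokosterone,C27H44O7,Steroids,NX,FALSE,26.94,
74,"2,15-Hexadecanedione",C16H30O2,Others,YYH,FALSE,28.62,
75,Yinyanghuo A,C25H24O6,Flavonoids,YYH,FALSE,29.06,
76,Artonin U,C21H20O5,Flavonoids,YYH,FALSE,29.63,
77,AstragalosideII_qt,C37H60O10,Triterpenoids,HQ,FALSE,29.76,
78,"8,3'-diprenylapigenin",C25H26O5,Flavonoids,YYH,FALSE,30.20,
79,DBP,C16H22O4,Others,NX,FALSE,32.96,
80,Oleanolic acid,C30H48O3,Triterpenoids,YYH;NX,FALSE,37.98,
81,Linolenic acid,C18H30O2,Organic acids,HQ,FALSE,38.19,
82,Rhamnocitrin-3-O-glucoside,C22H22O11,Flavonoids,HQ,FALSE,38.31,
83,EIC,C18H32O2,Organic acids,HQ,FALSE,41.16,
84,Baicalin,C21H18O11,Flavonoids,NX,FALSE,44.22,
85,Asernestioside A,C47H78O18,Triterpenoids,HQ,FALSE,46.85,
86,Rutin,C27H30O16,Flavonoids,YYH;NX;HQ,FALSE,46.86,
87,Asernestioside B,C49H80O19,Triterpenoids,HQ,FALSE,48.41,
88,Jaranol,C17H14O6,Flavonoids,HQ,FALSE,49.83,
89,Daucosterol,C35H60O6,Steroids,YYH;NX,FALSE,50.62,
90,Wanepimedoside A,C33H42O15,Flavonoids,YYH,FALSE,52.31,
91,Linoelaidyl acetate,C20H36O2,Others,YYH,FALSE,57.66,
92,"5'-Hydroxyiso-muronulatol-2',5'-di-O-glucoside",C29H38O16,Saccharide,HQ,FALSE,57.75,
93,Stigmasterol,C29H48O,Steroids,NX,FALSE,57.90,
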