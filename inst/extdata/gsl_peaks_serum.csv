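no,compound,rt_min,mz,polarity,adducts,printed_ppm,fragments,provenance
1,Chlorogenic acid,5.26,353.0846,-,[M-H]-,-9.2,93.0350,
2,Ecdysterone,8.40,481.3201,+,[M+H]+,8.5,175.1189;288.2025,
3,"1-O-{(3beta,5xi,9xi)-3-[(6-Methyl-beta-D-glucopyranuronosyl)oxy]-28-oxoolean-12-en-28-yl}-beta-D-glucopyranose",12.30,853.4568,-,[M+HCOO]-,-2.8,137.0231;312.1296,
4,Diphylloside A,12.72,823.2644,-,[M-H]-,-2.7,214.9992;312.1294,
5,Epimedoside D,13.01,793.2537,-,[M-H]-,-3.0,631.2019,
6,Epimedoside A,13.34,661.2083,-,[M-H]-;[M+HCOO]-,-8.3,353.0997,
7,Epimedin A,17.58,883.2807,-,[M+HCOO]-,-8.0,675.2247,formula per curated library entry C39H50O20
8,Epimedin B,18.44,853.2745,-,[M+HCOO]-;[M+Cl]-,-3.2,252.0406;366.1081;645.2177,formula per curated library entry C38H48O19
8,Epimedin B,18.44,809.2861,+,[M+H]+,-0.2,369.1333;531.1842,
9,Epimedin C,18.92,867.2915,-,[M+HCOO]-,-1.6,366.1059;659.2331,
9,Epimedin C,18.92,823.3031,+,[M+H]+,1.5,136.0765;531.1840,
10,Icariin,19.20,721.2341,-,[M+HCOO]-;[M+Cl]-,-1.2,367.1163,
10,Icariin,19.20,677.2413,+,[M+H]+,-4.0,313.0683;369.1314;531.1844,
11,Rubschisantherin,19.45,481.1812,+,[M+Na]+,-4.3,97.0644,
12,Achyranthoside D,21.12,1117.5037,-,[M-H]-,-3.2,217.0817;365.2313;413.1985;585.2846;785.4175,
13,Ginsenoside Ro,21.21,955.4937,-,[M-H]-,3.0,413.1985;585.2846;785.4175,
14,Achyranthoside C,21.92,955.4622,-,[M-H]-,8.2,353.2213;405.2627,
15,Sagittatoside B,22.99,645.2157,-,[M-H]-,-4.9,223.0270,
16,Icariside II,23.89,513.1739,-,[M-H]-,-5.3,366.1082,
16,Icariside II,23.89,515.1908,+,[M+H]+,-0.8,313.0671,
17,"2,15-Hexadecanedione",28.61,277.2140,+,[M+Na]+,0.6,223.1695,
18,DBP,32.96,301.1382,+,[M+Na]+;[M+H]+;[M+K]+,-9.4,149.0216,
19,Linolenic acid,38.18,279.2323,+,[M+H]+,1.7,95.0865,
20,Rutin,46.60,645.1256,-,[M+Cl]-,4.4,168.0420,
20,Rutin,46.60,633.1444,+,[M+Na]+;[M+K]+,2.8,207.0296,
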