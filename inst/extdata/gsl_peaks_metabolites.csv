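no,rt_min,mz,polarity,adducts,printed_ppm,prototype,identification,formula,provenance
M1,4.8,875.2792,-,[M+Cl]-,5.2,Epimedin C,Epimedin C + H2 + O,C39H52O20,
M2,7.4,646.2978,-,[M+HCOO]-,-5.8,Linolenic acid,Linolenic acid + H2O + C10H15N3O6S,C28H47N3O9S,
M3,7.57,696.3213,-,[M+Cl]-,3.2,Ecdysterone,Ecdysterone + H2 + H2O + C5H7NO3S,C32H55NO11S,
M4,7.72,591.2631,-,[M-H]-,9.3,Ecdysterone,Ecdysterone + 2x(+O) + HPO3,C27H45O12P,
M5,7.73,629.2539,-,[M+Cl]-,6.4,Ecdysterone,Ecdysterone + O + H2O + HPO3,C27H47O12P,
M6,7.89,493.1677,-,[M-H]-,8.9,Rubschisantherin,Rubschisantherin - COO + HPO3,C24H31O9P,
M7,8.24,535.1793,-,[M+HCOO]-,-5.2,Rubschisantherin,Rubschisantherin + 2x(+O),C25H30O10,
M8,8.41,852.3433,-,[M+Cl]-,8.4,Ecdysterone,Ecdysterone + 2x(+O) + C10H15N3O6S,C37H59N3O15S,
M9,14.8,429.193,-,[M-H]-,2.7,Rubschisantherin,Rubschisantherin + O - COO,C24H30O7,
M10,16.62,803.1385,-,[M+Cl]-,-7.2,Rutin,Rutin - H2O + C6H8O6,C33H36O21,
M11,19.74,865.2694,-,[M+HCOO]-,-8.9,Epimedin A,Epimedin A - H2O,C39H48O19,consistent with the curated epimedin A formula C39H50O20
M12,19.79,821.2456,-,[M-H]-,-6.6,Sagittatoside B,Sagittatoside B + C6H8O6,C38H46O20,
M13,20.03,413.199,-,[M-H]-,4.9,Rubschisantherin,Rubschisantherin - COO,C24H30O6,
M14,20.04,835.2618,-,[M+HCOO]-,-5.8,Epimedin B,Epimedin B - H2O,C38H46O18,printed adduct had spaces ([M + HCOO]-); consistent with the curated epimedin B formula C38H48O19
M15,22.34,497.3131,-,[M-H]-,2.2,Ecdysterone,Ecdysterone + H2O,C27H46O8,
M16,23.09,659.2317,-,[M-H]-,-4.3,Icariin,Icariin + H2 - H2O,C33H40O14,
M17,24.63,672.312,-,[M-H]-,9.1,Ecdysterone,Ecdysterone + 2x(+O) + C5H7NO3S,C32H51NO12S,
M18,26.05,313.2376,-,[M-H]-,-2.9,Linolenic acid,Linolenic acid + 2x(+H2O),C18H34O4,
M19,27.3,409.1519,-,[M+Cl]-,-8.1,Linolenic acid,Linolenic acid + O + HPO3,C18H31O6P,
M20,27.48,579.2972,-,[M-H]-,5.5,Ecdysterone,Ecdysterone + H2 + H2O + HPO3,C27H49O11P,
M21,27.59,586.3145,-,[M-H]-,-4.1,Linolenic acid,Linolenic acid + 2x(+H2) + C10H15N3O6S,C28H49N3O8S,
M22,27.85,630.3034,-,[M+HCOO]-,-5.3,Linolenic acid,Linolenic acid + H2 + C10H15N3O6S,C28H47N3O8S,
M23,27.88,309.2043,-,[M-H]-,-9.1,Linolenic acid,Linolenic acid + 2x(+O),C18H30O4,
M24,28.66,527.3212,-,[M+HCOO]-,-2.7,Ecdysterone,Ecdysterone + H2,C27H46O7,
M25,28.82,557.2997,-,[M+HCOO]-,5.4,Ecdysterone,Ecdysterone + 2x(+O),C27H44O9,
M26,28.83,616.2894,-,[M-H]-,-2.7,Linolenic acid,Linolenic acid + O + H2O + C10H15N3O6S,C28H47N3O10S,
M27,28.86,680.3184,-,[M+Cl]-,-8.6,Ecdysterone,Ecdysterone + 2x(+H2) + C5H7NO3S,C32H55NO10S,
M28,28.97,656.3155,-,[M-H]-,6.9,Ecdysterone,Ecdysterone + O + C5H7NO3S,C32H51NO11S,
M29,29.08,531.2733,-,[M+Cl]-,0.5,Ecdysterone,Ecdysterone + O,C27H44O8,
M30,30.24,295.2255,-,[M-H]-,-8,Linolenic acid,Linolenic acid + H2O,C18H32O3,
M31,31.03,520.2627,-,[M+HCOO]-,7.8,Linolenic acid,Linolenic acid + 2x(+H2O) + C5H7NO3S,C23H41NO7S,
M32,32.47,640.2711,-,[M+Cl]-,-0.7,Ecdysterone,Ecdysterone + 2x(-H2O) + C5H7NO3S,C32H47NO8S,
M33,34.78,347.1975,-,[M+Cl]-,-5.8,Linolenic acid,Linolenic acid + O + H2O,C18H32O4,
M34,34.9,638.2981,-,[M-H]-,-3.6,Ecdysterone,Ecdysterone + O - H2O + C5H7NO3S,C32H49NO10S,
M35,37.62,369.2044,-,[M-H]-,-7.4,Rubschisantherin,Rubschisantherin + 2x(-COO),C23H30O4,
M36,38.5,754.2396,-,[M+Cl]-,-3,Rubschisantherin,Rubschisantherin - COO + C10H15N3O6S,C34H45N3O12S,
M37,40.72,753.2191,-,[M+HCOO]-,-7.5,Icariin,Icariin + 2x(+O),C33H40O17,
M38,41.15,733.3252,-,[M+HCOO]-,-5,Ecdysterone,Ecdysterone + 2x(+O) + C6H8O6,C33H52O15,
M39,44.28,737.3607,-,[M+HCOO]-,0.7,Ecdysterone,Ecdysterone + 2x(+H2O) + C6H8O6,C33H56O15,
M40,51.66,803.1956,-,[M-H]-,8.5,Rutin,Rutin + H2O + C6H8O6,C33H40O23,
M41,53.66,921.2341,-,[M+Cl]-,-1.5,Epimedin C,Epimedin C + H2 - H2O + HPO3,C39H51O21P,
M42,53.67,916.2292,-,[M-H]-,-0.9,Rutin,Rutin + H2 + C10H15N3O6S,C37H47N3O22S,
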