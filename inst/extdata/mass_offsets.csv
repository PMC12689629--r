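delta_mass,label,category,composition
14.015650,methylation,metabolism,CH2
-14.015650,demethylation,metabolism,CH2
28.031300,ethylation,metabolism,C2H4
-28.031300,deethylation,metabolism,C2H4
26.015650,acetylation minus water,metabolism,C2H2
15.994915,oxidation,metabolism,O
-15.994915,deoxygenation,metabolism,O
31.989830,dioxidation,metabolism,O2
176.032090,glucuronidation,metabolism,C6H8O6
79.956816,sulfation,metabolism,SO3
-79.956816,desulfation,metabolism,SO3
42.010565,acetylation,metabolism,C2H2O
-42.010565,deacetylation,metabolism,C2H2O
18.010565,hydration,metabolism,H2O
-18.010565,dehydration,metabolism,H2O
-36.021130,double dehydration,metabolism,H4O2
2.015650,hydrogenation,metabolism,H2
-2.015650,dehydrogenation,metabolism,H2
30.010565,hydroxymethylation,metabolism,CH2O
-30.010565,formaldehyde loss,metabolism,CH2O
27.994915,formylation,metabolism,CO
-27.994915,decarbonylation,metabolism,CO
43.989830,carboxylation,metabolism,CO2
-43.989830,decarboxylation,metabolism,CO2
-46.005480,formic acid loss,metabolism,CH2O2
57.021464,glycine conjugation,metabolism,C2H3NO
71.037114,alanine conjugation,metabolism,C3H5NO
107.004100,taurine conjugation,metabolism,C2H5NO2S
-17.026549,deamination,metabolism,NH3
15.010899,amination,metabolism,NH
-35.976678,dehydrochlorination,metabolism,HCl
132.042260,pentose conjugation,metabolism,C5H8O4
162.052825,hexose conjugation,metabolism,C6H10O5
17.026549,ammonium adduct,adduct,NH3
21.981945,sodium adduct,adduct,
37.955882,potassium adduct,adduct,
37.946941,calcium adduct,adduct,
1.003355,carbon-13 isotope (+1),isotope,
2.006710,carbon-13 isotope (+2),isotope,
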