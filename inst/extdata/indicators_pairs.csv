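country,gni_per_capita,oda_per_capita,freshwater_per_capita,gini,government_effectiveness
EGY,1471,1.91,26.4,32.8,-0.16
JOR,1797,12.4,135.4,36.4,-0.01
PHL,1048,0.15,5917,46.1,-0.14
THA,1959,0.11,3519,42.8,0.20
TZA,297,1.04,2346,34.6,-0.42
UGA,264,1.44,1503,43.1,-0.38
CRI,3704,0.13,27456,46.5,0.25
DOM,2596,0.61,2350,52.0,-0.33
PRY,1346,0.07,16872,57.0,-1.17
PER,2052,0.65,60457,50.8,-0.09
KEN,421,0.85,627,42.5,-0.54
RWA,233,0.84,1057,51.5,-0.65
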