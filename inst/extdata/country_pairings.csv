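service,pair,country,iso3,cluster,region,normalized_rate,initial_coverage,gni_per_capita,oda_per_capita,freshwater_per_capita,gini,government_effectiveness
water,1,Egypt,EGY,3,Eastern Mediterranean,0.23,97.3,1471,1.91,26.4,32.8,-0.16
water,1,Jordan,JOR,3,Eastern Mediterranean,-0.38,96.7,1797,12.4,135.4,36.4,-0.01
water,2,Philippines,PHL,4,South-east Asia,-0.16,91.3,1048,0.15,5917,46.1,-0.14
water,2,Thailand,THA,4,South-east Asia,0.35,93.2,1959,0.11,3519,42.8,0.20
water,3,United Republic of Tanzania,TZA,5,East Africa,-0.01,55.5,297,1.04,2346,34.6,-0.42
water,3,Uganda,UGA,5,East Africa,0.66,56.8,264,1.44,1503,43.1,-0.38
sanitation,1,Costa Rica,CRI,3,Central America and the Caribbean,0.44,94.1,3704,0.13,27456,46.5,0.25
sanitation,1,Dominican Republic,DOM,3,Central America and the Caribbean,0.03,92.2,2596,0.61,2350,52.0,-0.33
sanitation,2,Paraguay,PRY,4,South America,0.42,65.2,1346,0.07,16872,57.0,-1.17
sanitation,2,Peru,PER,4,South America,0.05,68.8,2052,0.65,60457,50.8,-0.09
sanitation,3,Kenya,KEN,5,East Africa,0.20,50.3,421,0.85,627,42.5,-0.54
sanitation,3,Rwanda,RWA,5,Central/East Africa,1.0,52.0,233,0.84,1057,51.5,-0.65
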