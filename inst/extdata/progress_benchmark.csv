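country,iso3,water_n,water_year_first,water_year_last,water_r2,water_coverage_2000,water_rate,water_normalized,water_baseline_external,san_n,san_year_first,san_year_last,san_r2,san_coverage_2000,san_rate,san_normalized,san_baseline_external
Albania,ALB,5,2000,2009,0.30,97.1,-0.19,-0.57,FALSE,5,2000,2009,0.34,90.5,0.47,0.43,FALSE
Armenia,ARM,13,2000,2011,0.49,95.3,0.50,0.93,FALSE,NA,NA,NA,NA,NA,NA,NA,NA
Bangladesh,BGD,10,2000,2011,0.76,76.2,0.82,0.42,FALSE,10,2000,2011,0.83,68.4,1.51,0.77,FALSE
Belize,BLZ,5,2000,2009,0.65,89.3,0.85,0.77,FALSE,5,2000,2009,0.78,90.9,0.50,0.47,FALSE
Benin,BEN,6,2001,2009,0.17,66.1,0.57,0.25,TRUE,6,2001,2009,0.90,9.0,1.45,0.83,TRUE
Bolivia (Plurinational State of),BOL,10,2000,2009,0.74,80.1,1.00,0.57,FALSE,11,2000,2009,0.47,58.5,1.13,0.50,FALSE
Botswana,BWA,9,2000,2008,0.34,95.4,0.20,0.37,FALSE,8,2000,2008,0.48,60.3,0.88,0.40,FALSE
Brazil,BRA,21,2000,2011,0.54,91.8,0.30,0.34,FALSE,20,2000,2011,0.78,71.6,0.96,0.51,FALSE
Burkina Faso,BFA,11,2003,2010,0.35,59.9,1.08,0.45,TRUE,NA,NA,NA,NA,NA,NA,NA,NA
Cabo Verde,CPV,NA,NA,NA,NA,NA,NA,NA,NA,6,2000,2010,0.86,38.5,1.38,0.44,FALSE
Cambodia,KHM,8,2000,2011,0.51,46.8,1.77,0.72,FALSE,8,2000,2011,0.92,19.2,1.95,0.64,FALSE
Cameroon,CMR,5,2000,2007,0.35,59.4,1.03,0.42,FALSE,5,2000,2007,0.06,62.1,-0.38,-0.17,FALSE
Chad,TCD,5,2000,2010,0.47,46.3,0.15,0.06,FALSE,5,2000,2010,0.02,13.1,0.06,0.02,FALSE
Chile,CHL,5,2000,2009,0.89,94.9,0.47,0.81,FALSE,5,2000,2009,0.92,92.0,0.57,0.59,FALSE
Colombia,COL,NA,NA,NA,NA,NA,NA,NA,NA,5,2000,2010,0.68,84.2,1.12,0.76,FALSE
Costa Rica,CRI,11,2000,2011,0.16,95.2,0.16,0.29,FALSE,11,2000,2011,0.67,94.1,0.34,0.44,FALSE
Cote d'Ivoire,CIV,5,2000,2008,0.31,80.6,-0.92,-0.53,FALSE,5,2000,2008,0.02,40.6,0.20,0.06,FALSE
Democratic Republic of the Congo,COD,NA,NA,NA,NA,NA,NA,NA,NA,5,2001,2010,0.44,22.6,-1.41,-0.44,TRUE
Dominican Republic,DOM,NA,NA,NA,NA,NA,NA,NA,NA,6,2000,2010,0.01,92.2,0.03,0.03,FALSE
Egypt,EGY,5,2000,2008,0.83,97.3,0.07,0.23,FALSE,5,2000,2008,0.97,97.3,0.76,1.0,FALSE
Estonia,EST,5,2000,2003,0.25,98.9,-0.06,-0.49,FALSE,10,2000,2004,0.00,98.9,0.01,0.05,FALSE
Ethiopia,ETH,6,2000,2011,0.98,26.2,2.28,1.0,FALSE,7,2000,2011,0.89,11.9,2.20,0.97,FALSE
Georgia,GEO,NA,NA,NA,NA,NA,NA,NA,NA,6,2000,2010,0.70,97.5,-0.22,-0.59,FALSE
Ghana,GHA,9,2000,2008,0.87,66.5,2.29,1.0,FALSE,9,2000,2008,0.65,59.8,1.96,0.88,FALSE
Guatemala,GTM,7,2000,2009,0.19,86.4,0.41,0.31,FALSE,6,2000,2009,0.58,80.2,0.66,0.40,FALSE
Guinea,GIN,5,2002,2007,0.20,63.2,1.13,0.48,TRUE,5,2002,2007,0.75,14.1,1.96,0.76,TRUE
Guyana,GUY,5,2000,2009,0.50,88.8,0.50,0.44,FALSE,5,2000,2009,0.52,86.3,0.48,0.35,FALSE
Honduras,HND,14,2001,2011,0.75,80.8,0.75,0.43,TRUE,7,2001,2011,0.93,64.5,2.06,0.99,TRUE
India,IND,9,2000,2011,0.34,83.2,0.44,0.28,FALSE,9,2000,2011,0.97,31.5,1.48,0.45,FALSE
Indonesia,IDN,12,2001,2010,0.56,77.7,1.04,0.55,TRUE,NA,NA,NA,NA,NA,NA,NA,NA
Iraq,IRQ,5,2000,2011,0.33,82.6,0.87,0.54,FALSE,NA,NA,NA,NA,NA,NA,NA,NA
Jamaica,JAM,10,2000,2009,0.00,92.4,-0.00,-0.00,FALSE,10,2000,2009,0.04,97.0,0.03,0.07,FALSE
Jordan,JOR,5,2002,2010,0.10,96.7,-0.14,-0.38,TRUE,NA,NA,NA,NA,NA,NA,NA,NA
Kenya,KEN,7,2000,2010,0.27,52.9,0.70,0.28,FALSE,7,2000,2010,0.17,50.3,0.51,0.20,FALSE
Lao People's Democratic Republic,LAO,6,2000,2012,0.85,45.4,2.21,0.90,FALSE,9,2000,2012,0.89,26.6,3.16,0.95,FALSE
Lesotho,LSO,6,2000,2009,0.00,76.2,-0.04,-0.02,FALSE,5,2000,2009,0.28,32.8,0.25,0.08,FALSE
Liberia,LBR,6,2000,2011,0.30,60.5,1.11,0.46,FALSE,6,2000,2011,0.15,30.3,0.71,0.22,FALSE
Madagascar,MDG,9,2000,2011,0.78,33.6,1.33,0.56,FALSE,8,2000,2011,0.15,32.0,0.23,0.07,FALSE
Malawi,MWI,13,2000,2011,0.55,65.5,1.43,0.61,FALSE,11,2000,2011,0.47,74.6,0.90,0.50,FALSE
Mali,MLI,5,2001,2010,0.93,45.5,3.47,1.0,TRUE,6,2001,2010,0.20,18.2,0.32,0.11,TRUE
Mauritania,MRT,5,2000,2007,0.04,36.8,0.42,0.17,FALSE,5,2000,2007,0.84,27.1,1.51,0.42,FALSE
Mexico,MEX,9,2000,2010,0.52,87.2,0.78,0.61,FALSE,11,2000,2010,0.55,81.7,1.06,0.67,FALSE
Mongolia,MNG,5,2000,2007,0.77,66.8,1.54,0.67,FALSE,NA,NA,NA,NA,NA,NA,NA,NA
Morocco,MAR,10,2000,2007,0.88,74.0,1.29,0.63,FALSE,NA,NA,NA,NA,NA,NA,NA,NA
Mozambique,MOZ,5,2003,2009,0.58,41.1,1.48,0.61,TRUE,8,2001,2009,0.45,14.1,1.10,0.43,TRUE
Myanmar,MMR,NA,NA,NA,NA,NA,NA,NA,NA,6,2000,2010,0.43,71.4,1.28,0.68,FALSE
Namibia,NAM,5,2000,2007,0.21,77.6,0.80,0.43,FALSE,NA,NA,NA,NA,NA,NA,NA,NA
Nepal,NPL,7,2001,2011,0.11,77.4,0.32,0.17,TRUE,9,2000,2011,0.73,28.5,2.19,0.66,FALSE
Nicaragua,NIC,5,2001,2006,0.48,80.0,0.56,0.32,TRUE,NA,NA,NA,NA,NA,NA,NA,NA
Niger,NER,5,2000,2008,0.08,43.3,0.44,0.18,FALSE,NA,NA,NA,NA,NA,NA,NA,NA
Nigeria,NGA,10,2000,2011,0.55,54.0,0.77,0.31,FALSE,10,2000,2011,0.44,63.9,-1.02,-0.49,FALSE
Pakistan,PAK,12,2002,2009,0.02,88.3,0.15,0.13,TRUE,9,2002,2008,0.86,37.4,2.30,0.73,TRUE
Paraguay,PRY,6,2000,2004,0.23,77.0,0.95,0.49,FALSE,5,2000,2004,0.12,65.2,0.87,0.42,FALSE
Peru,PER,6,2000,2009,0.04,83.0,0.14,0.09,FALSE,6,2000,2009,0.01,68.8,0.09,0.05,FALSE
Philippines,PHL,6,2000,2008,0.21,91.3,-0.15,-0.16,FALSE,6,2000,2008,0.51,81.4,0.52,0.33,FALSE
Republic of Korea,KOR,7,2000,2006,0.99,93.5,0.50,0.69,FALSE,NA,NA,NA,NA,NA,NA,NA,NA
Republic of Moldova,MDA,13,2000,2010,0.40,93.0,0.35,0.46,FALSE,13,2000,2010,0.73,84.4,0.88,0.60,FALSE
Rwanda,RWA,11,2000,2010,0.00,68.7,0.06,0.03,FALSE,10,2000,2010,0.84,52.0,2.56,1.0,FALSE
Samoa,WSM,5,2001,2011,0.66,93.3,0.89,1.0,TRUE,NA,NA,NA,NA,NA,NA,NA,NA
Senegal,SEN,7,2000,2011,0.66,67.3,0.77,0.34,FALSE,8,2000,2011,0.46,56.3,0.82,0.35,FALSE
Sierra Leone,SLE,5,2003,2010,0.89,46.8,1.28,0.52,TRUE,7,2000,2011,0.33,37.0,0.67,0.21,FALSE
South Africa,ZAF,7,2000,2008,0.83,85.1,0.71,0.49,FALSE,8,2000,2008,0.13,74.3,0.58,0.32,FALSE
Sri Lanka,LKA,7,2000,2010,0.70,74.6,1.25,0.62,FALSE,5,2000,2010,0.61,89.2,1.06,0.90,FALSE
Swaziland,SWZ,5,2000,2010,0.59,51.8,1.21,0.49,FALSE,6,2000,2010,0.48,68.4,0.71,0.36,FALSE
Tajikistan,TJK,6,2000,2009,0.18,59.1,0.54,0.22,FALSE,5,2000,2007,0.62,59.1,0.80,0.35,FALSE
Thailand,THA,5,2000,2006,0.20,93.2,0.26,0.35,FALSE,5,2000,2006,0.16,99.1,-0.04,-0.27,FALSE
Timor-Leste,TLS,6,2001,2010,0.52,54.3,1.35,0.55,TRUE,6,2001,2010,0.02,37.4,0.17,0.05,TRUE
Uganda,UGA,10,2001,2010,0.77,56.8,1.61,0.66,TRUE,11,2000,2010,0.51,48.1,0.68,0.25,FALSE
United Republic of Tanzania,TZA,10,2000,2011,0.00,55.5,-0.03,-0.01,FALSE,10,2000,2011,0.70,14.0,0.88,0.34,FALSE
Uruguay,URY,5,2003,2011,0.00,97.9,-0.01,-0.03,TRUE,5,2003,2011,0.73,96.7,-0.16,-0.34,TRUE
Viet Nam,VNM,8,2000,2011,0.82,78.8,1.20,0.66,FALSE,8,2000,2011,0.52,61.2,1.20,0.55,FALSE
Zambia,ZMB,6,2002,2010,0.61,53.6,1.04,0.42,TRUE,7,2000,2010,0.02,56.9,0.11,0.05,FALSE
Zimbabwe,ZWE,5,2003,2011,0.09,79.6,-0.29,-0.17,TRUE,5,2003,2011,0.16,40.4,-0.34,-0.11,TRUE
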