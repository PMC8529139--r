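study_id,article_id,year,country,ethnicity_group,cancer_label,cancer_group,pancreatic,sample_source,sample_group,tp,fn,fp,tn,sample_size,cutoff
Akers2013,Akers2013,2013,United States,caucasian,Glioma,other,FALSE,CSF-EV,other,11,2,0,14,27,0.25
Ando2019,Ando2019,2019,Japan,asian,BC,breast,FALSE,Urine,other,16,6,5,21,48,0.413
Butz2015,Butz2015,2015,Canada,caucasian,RCC,other,FALSE,Urine,other,20,8,4,14,46,-6.9
Goto2018_IPMN,Goto2018,2018,Japan,asian,IPMN,other,TRUE,Serum,serum,22,7,4,18,51,median miR-21 value
Goto2018_PCearly,Goto2018,2018,Japan,asian,PC(early),digestive,TRUE,Serum,serum,6,3,4,18,31,median miR-21 value
Goto2018_PCadv,Goto2018,2018,Japan,asian,PC(advanced),digestive,TRUE,Serum,serum,20,3,4,18,45,median miR-21 value
HernandezWalias2020,HernandezWalias2020,2020,Spain,caucasian,Lymphoma,other,FALSE,Plasma,plasma,25,12,21,53,111,6.171
Jin2019,Jin2019,2019,China,asian,CRC,digestive,FALSE,Serum,serum,11,0,14,18,43,Youden index
Kawamura2018_PV,Kawamura2018,2018,Japan,asian,PC,digestive,TRUE,Portal vein blood,other,24,9,6,16,55,1.18
Kawamura2018_PB,Kawamura2018,2018,Japan,asian,PC,digestive,TRUE,Peripheral blood,other,18,15,8,14,55,1.18
Lai2017,Lai2017,2017,United States,caucasian,PC,digestive,TRUE,Plasma,plasma,29,0,0,6,35,1.38
Liu2014,Liu2014,2014,China,asian,Glioma,other,FALSE,CLF exosome,other,40,5,0,25,70,NR
Liu2020_S1,Liu2020,2020,United States,caucasian,LC,lung,FALSE,Serum,serum,53,11,2,13,79,NR
Liu2020_S2,Liu2020,2020,United States,caucasian,LC,lung,FALSE,Serum,serum,29,35,3,12,79,NR
Matsuzaki2017,Matsuzaki2017,2017,Japan,asian,UC,other,FALSE,Urine,other,27,9,1,23,60,Youden index
Melo2014,Melo2014,2014,United States,caucasian,BC,breast,FALSE,Serum,serum,9,2,0,8,19,NR
Nakamura2019,Nakamura2019,2019,Japan,asian,PDAC,digestive,TRUE,Pancreatic Juice,other,22,5,1,7,35,Youden index
OgataKawata2014,OgataKawata2014,2014,Japan,asian,CC,other,FALSE,Serum,serum,54,34,2,9,99,1.08
Pan2018,Pan2018,2018,Germany,caucasian,OC,other,FALSE,Plasma,plasma,65,41,5,24,135,NR
Que2013,Que2013,2013,China,asian,PC,digestive,TRUE,Serum,serum,21,1,5,22,49,7.693
Soeda2019,Soeda2019,2019,Japan,asian,GC,digestive,FALSE,Plasma,plasma,45,28,13,43,129,0.93
Tanaka2013,Tanaka2013,2013,Japan,asian,ESCC,digestive,FALSE,Serum,serum,28,16,6,35,85,median miR-21 value
Taylor2008,Taylor2008,2008,United States,caucasian,CRC,digestive,FALSE,Serum,serum,30,0,0,10,40,NR
Tokuhisa2015,Tokuhisa2015,2015,Japan,asian,HCC,other,FALSE,PLF exosome,other,8,1,2,7,18,NR
Tsukamoto2017,Tsukamoto2017,2017,Japan,asian,CRC,digestive,FALSE,Plasma,plasma,78,72,72,104,326,median miR-21 value
Uratani2016,Uratani2016,2016,Japan,asian,CRC,digestive,FALSE,Serum,serum,18,8,9,38,73,Youden index
Wang2014,Wang2014,2014,China,asian,CRC,digestive,FALSE,Serum,serum,9,4,12,18,43,5 fold
Wang2020,Wang2020,2020,China,asian,HCC,other,FALSE,Plasma,plasma,41,9,4,46,100,NR
WangJ2014,WangJ2014,2014,China,asian,LSCC,other,FALSE,Serum,serum,36,16,9,40,101,0.043
Yang2020,Yang2020,2020,China,asian,LC,lung,FALSE,Serum,serum,61,14,7,17,99,NR
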