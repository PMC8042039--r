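group_id,pooled_group,n,place,LAT,LON,TMN,TMX,HMN,HMX,role
Chinese,Chinese,22,"Guangzhou, Guangdong Province",23.13,113.25,9.63,32.48,11.36,31.56,modern
Barrow_Quad,Inuits,9,"Point Barrow, Alaska",71.40,-156.48,-30.37,8.28,0.44,7.85,modern
Tigara_Village,Inuits,20,"Point Hope, Alaska",68.35,-166.80,-25.35,13.69,0.51,8.83,modern
Buryats,Mong-Bur,14,"Nr. Lake Baikal",52.28,104.32,-24.32,24.87,1.20,15.14,modern
Mongolians,Mong-Bur,32,"Mongolian Urga",47.92,106.91,-28.87,23.02,0.63,11.17,modern
Tepe_Hissar,Iran,19,"Damghan, Iran",36.16,54.39,-4.99,32.73,2.94,10.01,modern
Former_Yugoslavia,Euro-Centr,8,"Dubrovnik, Croatia",42.64,18.11,-0.92,27.38,5.47,14.99,modern
Germany,Euro-Centr,7,"Frankfurt",50.11,8.68,-2.88,24.04,5.79,14.40,modern
Netherlands,Euro-Centr,2,"Amsterdam",52.38,4.90,0.41,21.28,6.74,15.41,modern
Scandinavia,Euro-Scand,10,"Nr. Falun, Sweden",61.33,15.27,-12.39,20.04,3.24,12.11,modern
Egyptians,North-Afr,15,"Cairo",30.06,31.24,18,35,10,22,modern
Nubians,Sudanese,22,"Northern Dongola",18.28,30.38,10,43.5,6.5,14.5,modern
Kenyans,East-Afr,18,"Nairobi",-1.30,37.51,1.95,28.32,13.59,17.34,modern
Cote_dIvoire,West-Afr,9,"Cote d'Ivoire",6.50,-4.70,20.95,34.12,24.59,28.54,modern
Gabon,West-Afr,9,"Gabon",-0.72,8.78,20.98,30.92,24.52,30.27,modern
Khoisan,South-Afr,14,"Kareeberg, Northern Cape",-30.56,22.94,-0.2,31,5,12,modern
Sungir,Sungir,1,"Vladimir, Russia",56.2,40.3,-13.53,24.04,2.64,15.29,fossil
Mladec,Mladec,1,"Detcovice, Czech Republic",49.42,17.1,-4.05,24.46,4.49,14.69,fossil
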