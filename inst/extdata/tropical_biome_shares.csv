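biome,pct_area,pct_locations,loc_density,pct_citations,cit_density,ratio
"Grasslands, Savannas & Shrublands",31.1,11.2,5.2,10.7,66,1.0
"Moist Broadleaf Forests",28.5,68.2,34.9,73.4,493,1.1
"Deserts & Xeric Shrublands",20.2,1.1,0.8,1.3,12,1.2
"Dry Broadleaf Forests",5.6,9.1,23.5,8.1,275,0.9
"Montane Grasslands & Shrublands",4.4,0.9,3.0,1.1,48,1.2
"Flooded Grasslands & Savannas",1.2,0.7,8.2,0.4,62,0.6
"Coniferous Forests",1,1.9,27.8,0.6,115,0.3
"Mangroves",0.5,2.1,63.4,1.9,752,0.9
"Extra-tropical other",7.5,4.8,9.4,2.6,67,0.5
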