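area_id,name,pharmacists,population,aging_rate,land_area_km2
Total,Total,6234,5371742,0.290,78454
Sapporo,Sapporo,3039,2375449,0.252,3540
Kamikawachubu,Kamikawachubu,501,394270,0.321,4238
Minamioshima,Minamioshima,526,381629,0.323,2671
Tokachi,Tokachi,343,343436,0.288,10828
Kushiro,Kushiro,258,236516,0.304,5998
Hokumo,Hokumo,196,222696,0.308,5542
Shiribeshi,Shiribeshi,255,215522,0.356,4306
Higashiiburi,Higashiiburi,209,212059,0.281,2340
Nishiiburi,Nishiiburi,204,189696,0.294,1357
Minamisorachi,Minamisorachi,164,166691,0.355,2562
Nakasorachi,Nakasorachi,114,108970,0.379,2162
Nemuro,Nemuro,45,76621,0.268,3533
Emmon,Emmon,33,70846,0.347,5148
Hidaka,Hidaka,73,69015,0.315,4811
Soya,Soya,61,67503,0.303,4626
Kamikawahokubu,Kamikawahokubu,57,66591,0.344,4197
Rumoi,Rumoi,50,47912,0.363,3446
Kitaoshimahiyama,Kitaoshimahiyama,30,37279,0.356,2474
Kitasorachi,Kitasorachi,20,32675,0.403,1067
Furano,Furano,42,36550,0.404,2183
Minamihiyama,Minamihiyama,14,23769,0.375,1423
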