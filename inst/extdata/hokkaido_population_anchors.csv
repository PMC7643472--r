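area_id,pop_2015,pop_2025,pop_2040
Total,5371742,5016554,4280427
Sapporo,2375449,2377341,2218734
Kamikawachubu,394270,365532,306101
Minamioshima,381629,331212,252822
Tokachi,343436,325611,288298
Kushiro,236516,208707,162733
Hokumo,222696,198393,157087
Shiribeshi,215522,178117,126583
Higashiiburi,212059,198637,169906
Nishiiburi,189696,164447,125020
Minamisorachi,166691,137171,96651
Nakasorachi,108970,89175,62271
Nemuro,76621,67104,52154
Emmon,70846,59055,42381
Hidaka,69015,56314,39100
Soya,67503,54985,38020
Kamikawahokubu,66591,55731,40414
Rumoi,47912,37857,24856
Kitaoshimahiyama,37279,29650,20065
Kitasorachi,32675,26651,18318
Furano,36550,32597,27436
Minamihiyama,23769,18314,11477
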