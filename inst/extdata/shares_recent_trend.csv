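area_id,share
Sapporo,0.647
Kamikawachubu,0.086
Minamioshima,0.025
Tokachi,0.042
Kushiro,0.032
Hokumo,0.003
Shiribeshi,0.039
Higashiiburi,0.021
Nishiiburi,0.007
Minamisorachi,0.030
Nakasorachi,-0.005
Nemuro,0.005
Emmon,0.033
Hidaka,0.019
Soya,-0.008
Kamikawahokubu,0.015
Rumoi,0.001
Kitaoshimahiyama,-0.004
Kitasorachi,-0.001
Furano,0.012
Minamihiyama,0.001
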