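area_id,share
Sapporo,0.560
Kamikawachubu,0.107
Minamioshima,0.077
Tokachi,0.042
Kushiro,0.041
Hokumo,0.042
Shiribeshi,0.014
Higashiiburi,0.046
Nishiiburi,0.040
Minamisorachi,-0.002
Nakasorachi,0.018
Nemuro,-0.006
Emmon,0.008
Hidaka,0.005
Soya,0.002
Kamikawahokubu,0.006
Rumoi,-0.002
Kitaoshimahiyama,0.007
Kitasorachi,-0.002
Furano,-0.008
Minamihiyama,0.004
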