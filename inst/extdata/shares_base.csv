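area_id,share
Sapporo,0.500
Kamikawachubu,0.082
Minamioshima,0.076
Tokachi,0.055
Kushiro,0.039
Hokumo,0.030
Shiribeshi,0.042
Higashiiburi,0.033
Nishiiburi,0.032
Minamisorachi,0.025
Nakasorachi,0.018
Nemuro,0.007
Emmon,0.006
Hidaka,0.012
Soya,0.008
Kamikawahokubu,0.010
Rumoi,0.007
Kitaoshimahiyama,0.004
Kitasorachi,0.003
Furano,0.007
Minamihiyama,0.002
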