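"model","predictor","estimate","ci_lo","ci_hi"
"adopt_fert","intercept",0.6,0.45,0.75
"adopt_fert","subsidy_share",1.2,0.9,1.5
"adopt_fert","livestock_tlu",0.05,0.0375,0.0625
"adopt_fert","education",0.03,0.0225,0.0375
"adopt_fert","legume_planted",0.3,0.225,0.375
"adopt_fert","farm_type2",0.3,0.225,0.375
"adopt_fert","farm_type3",0.6,0.45,0.75
"qty_fert","intercept",3.9,3.75,4.05
"qty_fert","subsidy_share",0.5,0.375,0.625
"qty_fert","farm_type2",0.25,0.1875,0.3125
"qty_fert","farm_type3",0.5,0.375,0.625
"qty_fert","soil_n_100",-0.01,-0.0125,-0.0075
"adopt_manure","intercept",-0.2,-0.35,-0.05
"adopt_manure","subsidy_share",-0.8,-1,-0.6
"adopt_manure","livestock_tlu",0.15,0.1125,0.1875
"adopt_manure","farm_type3",0.5,0.375,0.625
"qty_manure","intercept",6,5.85,6.15
"qty_manure","livestock_tlu",0.1,0.075,0.125
"qty_manure","farm_type3",0.4,0.3,0.5
"adopt_legume","intercept",-0.7,-0.85,-0.55
"adopt_legume","subsidy_share",0.6,0.45,0.75
"adopt_legume","education",0.04,0.03,0.05
"share_legume","intercept",-1.2,-1.35,-1.05
"share_legume","education",0.02,0.015,0.025
"adopt_swc","intercept",-2.5,-2.65,-2.35
"adopt_swc","slope_pct",0.08,0.06,0.1
"yield_maize","intercept",6.7,6.55,6.85
"yield_maize","soil_n_100",0.015,0.01125,0.01875
"yield_maize","fert_kg_100",0.12,0.09,0.15
"yield_maize","manure_t",0.05,0.0375,0.0625
"yield_maize","cultivation_period",-0.01,-0.0125,-0.0075
"yield_maize","farm_type3",0.2,0.15,0.25
"yield_maize","slope_pct",-0.005,-0.00625,-0.00375
"yield_legume","intercept",6.2,6.05,6.35
"yield_legume","soil_p_100",0.01,0.0075,0.0125
"yield_legume","cultivation_period",-0.008,-0.01,-0.006
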