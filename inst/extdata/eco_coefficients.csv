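"name","estimate","lo","hi","units"
"dep_a_n",0.14,0.112,0.168,"kg/ha per sqrt(mm)"
"dep_a_p",0.025,0.02,0.03,"kg/ha per sqrt(mm)"
"dep_a_k",0.05,0.04,0.06,"kg/ha per sqrt(mm)"
"manure_n",0.012,0.0096,0.0144,"fraction"
"manure_p",0.003,0.0024,0.0036,"fraction"
"manure_k",0.01,0.008,0.012,"fraction"
"manure_c",0.3,0.24,0.36,"fraction"
"residue_n",0.007,0.0056,0.0084,"fraction"
"residue_p",0.001,8e-04,0.0012,"fraction"
"residue_k",0.012,0.0096,0.0144,"fraction"
"residue_c",0.4,0.32,0.48,"fraction"
"avail_n",0.5,0.4,0.6,"fraction"
"avail_p",0.6,0.48,0.72,"fraction"
"avail_k",0.8,0.64,0.96,"fraction"
"humification",0.3,0.24,0.36,"fraction"
"k_soc",0.02,0.016,0.024,"1/yr"
"ndfa",0.6,0.48,0.72,"fraction"
"legume_n",0.025,0.02,0.03,"fraction"
"rusle_r_per_mm",0.5,0.4,0.6,"MJ mm/(ha h yr) per mm rain"
"rusle_k",0.02,0.016,0.024,"t ha h/(ha MJ mm)"
"rusle_c_cover",0.3,0.24,0.36,"unitless"
"p_swc",0.5,0.4,0.6,"unitless"
"er_n",2,1.6,2.4,"unitless"
"er_p",2,1.6,2.4,"unitless"
"er_k",1.5,1.2,1.8,"unitless"
"er_c",2,1.6,2.4,"unitless"
"sdr",0.3,0.24,0.36,"fraction"
"leach_rate",0.25,0.2,0.3,"fraction per m rain"
"leach_clay_max",60,48,72,"%"
"mineral_n_frac",0.02,0.016,0.024,"fraction"
"mineral_k_frac",0.02,0.016,0.024,"fraction"
"gas_base",0.05,0.04,0.06,"fraction"
"gas_rain",0.1,0.08,0.12,"fraction per m rain"
"hi_maize",0.45,0.36,0.54,"fraction"
"hi_legume",0.35,0.28,0.42,"fraction"
"grain_n_maize",0.016,0.0128,0.0192,"fraction"
"grain_p_maize",0.003,0.0024,0.0036,"fraction"
"grain_k_maize",0.004,0.0032,0.0048,"fraction"
"grain_n_legume",0.035,0.028,0.042,"fraction"
"grain_p_legume",0.004,0.0032,0.0048,"fraction"
"grain_k_legume",0.01,0.008,0.012,"fraction"
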