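"model","link","bound_min","bound_max"
"adopt_fert","logit",0,1
"qty_fert","log",0,400
"adopt_manure","logit",0,1
"qty_manure","log",0,8000
"adopt_legume","logit",0,1
"share_legume","logit",0,0.8
"adopt_swc","logit",0,1
"yield_maize","log",0,6000
"yield_legume","log",0,3000
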