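"id","formula","phase"
"cmpd01","C2H6O","liquid"
"cmpd02","C3H6O","liquid"
"cmpd03","C2H6O","liquid"
"cmpd04","C2H5Cl","liquid"
"cmpd05","C6H6","gas"
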