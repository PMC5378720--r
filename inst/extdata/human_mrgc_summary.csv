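subtype,count_whole_retina,density_sup_nasal_cells_per_mm2,layer
M1,988,0.51,GCL
M1d,1874,2.05,INL
M2,802,0.65,GCL
M3,1036,0.97,GCL
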