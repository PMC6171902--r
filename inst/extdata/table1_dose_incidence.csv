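group_label,dose,n_animals,n_tumor
hiPSC_clumps,0,6,0
hiPSC_clumps,100,6,2
hiPSC_clumps,1000,6,2
hiPSC_clumps,10000,6,6
single_hiPSC_NHDF,0,6,0
single_hiPSC_NHDF,10,6,0
single_hiPSC_NHDF,100,6,0
single_hiPSC_NHDF,1000,6,0
single_hiPSC_NHDF,10000,6,5
single_hiPSC_NHDF_Y27632,0,10,0
single_hiPSC_NHDF_Y27632,10,10,0
single_hiPSC_NHDF_Y27632,100,10,2
single_hiPSC_NHDF_Y27632,1000,10,7
single_hiPSC_NHDF_Y27632,10000,10,8
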