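condition,total_cells,marker_positive,total_sd,marker_sd
SPRPix,2600,930,364,148
rSS-PCL,1850,174,296,29
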