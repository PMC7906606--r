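time_h,chloroplast_volume_um3,chloroplast_volume_sd,thylakoid_surface_um2,thylakoid_surface_sd,thylakoid_envelope_ratio,thylakoid_envelope_ratio_sd,chloroplasts_per_cell,chloroplasts_per_cell_sd,cell_volume_um3,cell_volume_sd,cells_per_seedling
0,12.27,2.3,,,,,22,6,1173,284,
4,9.4,4.8,67,29.5,1.02,0.15,25,8,1891,362,3000
24,62,2.04,1476,146,7.37,0.51,26,6,6103,1309,3000
96,112.14,4.3,2086,393,6.83,1.40,112,29,52597,12671,3000
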