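patient,segment,cylinder_height_mm,cylinder_radius_mm,v_pre_mm3,v_post_mm3,delta_v_mm3,sd_delta_v_mm3,cv_delta_v
P01,L4-L5,90,11,23173.72,26760.96,3587.24,216.62,0.06
P02,L2-L3,90,10,22259.45,24031.61,1772.16,78.81,0.04
P02,L3-L4,90,11,25816.38,28998.01,3181.62,91.77,0.03
P02,L4-L5,90,10,18533.00,22001.31,3468.31,79.20,0.02
P03,L5-S1,90,10,10815.84,14296.92,3481.09,140.95,0.04
P04,L3-L4,90,12,31104.05,33326.11,2222.06,106.59,0.05
P05,L5-S1,90,11,14625.24,18575.94,3950.70,87.83,0.02
P06,L1-L2,90,10,21080.61,22532.95,1452.34,59.83,0.04
P07,L2-L3,90,10,21513.30,22970.16,1456.87,64.30,0.04
P07,L3-L4,90,10,20396.61,22698.79,2302.18,167.90,0.07
P07,L4-L5,90,10,18468.15,21559.50,3091.35,114.93,0.04
P08,L3-L4,90,11,24068.52,25273.62,1205.09,267.77,0.22
P08,L4-L5,90,12,26523.69,30013.21,3489.52,305.05,0.09
P09,Th12-L1,90,10,22695.25,23792.51,1097.26,145.93,0.13
P09,L1-L2,90,10,22351.12,22898.23,547.11,51.89,0.09
P10,L1-L2,90,10,23986.02,24403.36,417.34,49.25,0.12
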