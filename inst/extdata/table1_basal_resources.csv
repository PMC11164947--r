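label,n,d13c_mean,d13c_sd,d15n_mean,d15n_sd,pct_c,pct_n,cn_ratio,species
Fresh leaves,5,-15.1,0.7,0.2,1.5,45.5,1.4,34.9,Stipagrostis sabulicola
Dead leaves,7,-14.0,0.6,-1.9,1.6,43.0,0.5,88.5,Stipagrostis sabulicola
Fungal-infected dead leaves,12,-14.0,0.5,-0.7,2.5,43.8,0.9,57.0,Stipagrostis sabulicola
Root,6,-14.1,0.3,0.1,1.4,45.8,0.6,71.8,Stipagrostis sabulicola
Rhizosheath,8,-13.7,0.4,0.8,0.4,20.4,0.5,43.5,Stipagrostis sabulicola
Soil detritus,7,-14.3,0.2,2.0,1.2,34.5,0.9,38.8,Stipagrostis sabulicola
Litter (dead stem),8,-21.7,0.8,4.2,1.6,43.3,1.6,38.2,Acanthosicyos horridus
Soil detritus (A. horridus),6,-17.1,1.2,3.7,0.2,28.8,1.1,27.5,Acanthosicyos horridus
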