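label,n,pooled,d13c_mean,d13c_sd,d15n_enrichment,d15n_sd,baseline
Zygoribatula sp.,5,1,-14.7,0.7,0.05,0.6,Dead leaves
Diaspididae sp.,5,1,-15.7,0.8,0.9,0.6,Dead leaves
Liposcelis sp.,9,0,-20.6,3.3,2.8,1.9,Dead leaves
Deltocephalinae sp.,3,0,-13.9,0.4,3.2,1.2,Dead leaves
Thysanina sp.,1,0,-12.8,,4.0,,Dead leaves
Nanolpium sp.,4,0,-18.4,2.5,5.5,0.7,Dead leaves
Cybocephalus sp.,4,0,-13.5,0.2,5.9,2.8,Dead leaves
Camponotus detritus,6,0,-15.8,1.8,6.6,0.9,Dead leaves
Onymacris plana,8,0,-17.2,1.2,7.5,2.1,Dead leaves
Physadesmia globosa,4,0,-25.4,0.6,7.6,2.1,Dead leaves
Hycleus zigzagus,2,0,-18.4,0.6,10.4,1.1,Litter (dead stem)
Salticinae sp.,2,0,-14.1,0.3,10.9,0.9,Dead leaves
Haplothrips sp.,6,0,-17.8,1.9,11.4,2.5,Dead leaves
Sibinia sp.,5,0,-21.0,1.6,13.7,1.4,Dead leaves
Haltichellinae sp.,2,0,-14.0,0.3,16.7,0.4,Dead leaves
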